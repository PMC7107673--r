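test_that("Unknown encoding touches only missing categorical cells", {
  df <- data.frame(a = c("yes", NA, "no"), x = c(1, NA, 3),
                   stringsAsFactors = FALSE)
  enc <- encodeUnknown(df)
  expect_identical(enc$a, c("yes", "Unknown", "no"))
  expect_identical(enc$x, df$x)                  # continuous NA untouched
  expect_identical(encodeUnknown(enc), enc)      # fully observed unchanged
})

test_that("KNN imputation reproduces hand-computed medians and is row-local", {
  # exact-match neighbor at k = 1
  train <- data.frame(a = c(1, 5, 9), x = c(10, 20, 90))
  st1 <- fitImputer(train, k = 1)
  q <- data.frame(a = 5, x = NA_real_)
  expect_equal(imputeTable(st1, q)$x, 20)

  # 3-row worked example: query nearest the first two rows, k = 2
  toy <- data.frame(a = c(1, 1.1, 9), x = c(10, 20, 90))
  st2 <- fitImputer(toy, k = 2)
  expect_equal(imputeTable(st2, data.frame(a = 1.05, x = NA_real_))$x,
               median(c(10, 20)))

  # complete rows come back unchanged
  full <- data.frame(a = 2, x = 7)
  expect_identical(imputeTable(st2, full), full)

  # training state only: result independent of the other query rows
  q2 <- data.frame(a = c(1.05, 8.9), x = c(NA_real_, NA_real_))
  joint <- imputeTable(st2, q2)
  solo <- rbind(imputeTable(st2, q2[1, ]), imputeTable(st2, q2[2, ]))
  expect_equal(joint$x, solo$x)

  # all-missing distance basis falls back to the training median
  q3 <- data.frame(a = NA_real_, x = NA_real_)
  expect_equal(imputeTable(st2, q3)$x, median(toy$x))
})

test_that("stepwise logistic keeps signal, rejects noise, ignores row order", {
  set.seed(77)
  n <- 500
  noise <- as.data.frame(matrix(rnorm(n * 10), n, 10))
  y <- rbinom(n, 1, 0.45) == 1
  f0 <- fitStepwiseLogistic(noise, y)
  expect_lte(length(f0$selected), 1)   # chance level at alpha = 0.05 x 10

  strong <- data.frame(s = as.numeric(y) * 2 + rnorm(n, 0, 0.8), junk = rnorm(n))
  f1 <- fitStepwiseLogistic(strong, y)
  expect_true("s" %in% f1$selected)
  expect_gt(coef(f1$fit)[["s"]], 0)

  perm <- sample(n)
  f2 <- fitStepwiseLogistic(strong[perm, ], y[perm])
  expect_setequal(f1$selected, f2$selected)
})

test_that("random forest is seeded with calibrated probabilities", {
  set.seed(10)
  n <- 160
  y <- rep(c(TRUE, FALSE), each = n / 2)
  tab <- data.frame(u = as.numeric(y) * 3 + rnorm(n),
                    v = rnorm(n),
                    g = sample(c("a", "b"), n, TRUE), stringsAsFactors = FALSE)
  m1 <- trainLevelModel("rf", tab, y, seed = 4)
  m2 <- trainLevelModel("rf", tab, y, seed = 4)
  p1 <- predictModel(m1, tab); p2 <- predictModel(m2, tab)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_gte(rocAUC(y, p1), 0.95)      # linearly separable construction
})

test_that("the SVM demands a feature list and calibrates monotonically", {
  set.seed(11)
  n <- 120
  y <- rep(c(TRUE, FALSE), each = n / 2)
  tab <- data.frame(u = as.numeric(y) * 4 + rnorm(n, 0, 0.3), v = rnorm(n))
  expect_error(fitSVM(tab, y, feature_list = NULL), "feature list")

  f <- fitSVM(tab, y, feature_list = c("u", "v"), seed = 2)
  X <- strokehier:::.designMatrix(tab, f$template)
  pr <- predict(f$fit, X, probability = TRUE, decision.values = TRUE)
  probs <- attr(pr, "probabilities")[, "1"]
  dec <- as.numeric(attr(pr, "decision.values"))
  # Platt-type calibration is monotone in the decision value
  expect_equal(abs(cor(rank(probs), rank(dec))), 1, tolerance = 1e-9)
  acc <- mean((probs >= 0.5) == y)
  expect_equal(acc, 1)                 # separable toy
})

test_that("gradient boosting consumes raw missingness end to end", {
  set.seed(12)
  n <- 600
  # missingness itself is informative: the ordinal score is mostly
  # unrecorded for negatives, and median imputation collides the missing
  # mass with genuine mid-scale values
  y <- rbinom(n, 1, 0.5) == 1
  x <- rbinom(n, 4, 0.35 + 0.2 * y) + 1
  miss <- (!y & runif(n) < 0.75) | (y & runif(n) < 0.1)
  x[miss] <- NA
  tab <- data.frame(x = x, z = rnorm(n))
  tr <- 1:400; te <- 401:600
  m <- trainLevelModel("xgb", tab[tr, ], y[tr], seed = 6)
  expect_null(m@imputer)
  expect_true(all(m@importance >= 0))

  row <- tab[1, ]; row$x <- NA; row$z <- NA   # fully missing row predicts
  expect_true(is.finite(predictModel(m, row)))

  auc_raw <- rocAUC(y[te], predictModel(m, tab[te, ]))
  med <- tab
  med$x[is.na(med$x)] <- median(tab$x[tr], na.rm = TRUE)
  m2 <- trainLevelModel("xgb", med[tr, ], y[tr], seed = 6)
  auc_med <- rocAUC(y[te], predictModel(m2, med[te, ]))
  expect_gt(auc_raw, auc_med)          # default directions exploit missingness
})

test_that("importance reports scale to 1 and drop sub-0.01 scores", {
  expect_equal(importanceReport(c(a = 5)), c(a = 1))
  expect_equal(importanceReport(c(a = 10, b = 2)), c(a = 1, b = 0.2))
  rep3 <- importanceReport(c(a = 10, b = 2, c = 0.01))
  expect_false("c" %in% names(rep3))   # 0.001 scaled score omitted
  expect_equal(unname(rep3[1]), 1)
  expect_false(is.unsorted(rev(rep3)))
  expect_error(importanceReport(numeric(0)), "importance")
})
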