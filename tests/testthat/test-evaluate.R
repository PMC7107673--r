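test_that("the Youden index is exact arithmetic", {
  expect_equal(youden(1, 1), 1)
  expect_equal(youden(0.5, 0.5), 0)
  g <- youden(41 / 43, 39 / 57)
  expect_equal(round(100 * g, 1), 63.8)
  expect_error(youden(1.2, 0.5), "sensitivity")
})

test_that("cutoff selection equals the exhaustive-threshold oracle", {
  set.seed(21)
  for (rep in 1:8) {
    n <- sample(20:100, 1)
    labels <- rbinom(n, 1, 0.4) == 1
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), 2)       # ties on purpose
    got <- bestCutoff(labels, scores)
    # oracle: dense scan over a fine grid plus all observed values
    grid <- sort(unique(c(scores, seq(0, 1, by = 0.001))))
    g <- vapply(grid, function(ct) {
      pred <- scores >= ct
      sum(pred & labels) / sum(labels) + sum(!pred & !labels) / sum(!labels) - 1
    }, numeric(1))
    expect_equal(got$gamma, max(g), tolerance = 1e-12)
    # the returned cutoff attains the maximum and is the smallest candidate
    att <- scores >= got$cutoff
    expect_equal(sum(att & labels) / sum(labels) +
                 sum(!att & !labels) / sum(!labels) - 1, got$gamma)
    smaller <- sort(unique(scores))
    smaller <- smaller[smaller < got$cutoff]
    for (ct in smaller) {
      pred <- scores >= ct
      expect_lt(sum(pred & labels) / sum(labels) +
                sum(!pred & !labels) / sum(!labels) - 1, got$gamma)
    }
  }
})

test_that("cross-validated cutoff selection is stratified and sane", {
  set.seed(22)
  n <- 200
  y <- rep(c(TRUE, FALSE), each = n / 2)
  tab <- data.frame(u = as.numeric(y) * 3 + rnorm(n), v = rnorm(n))
  cv <- selectCutoffCV("xgb", tab, y, cutoffConfig(seed = 5))
  expect_gt(cv$gamma, 0.8)
  expect_true(cv$cutoff > 0 && cv$cutoff < 1)
  expect_equal(sort(unique(table(cv$fold, y)[, 1])), 10)  # 10 per fold per class

  # label-permuted data: the optimized gamma stays in the chance band
  yp <- sample(y)
  cvp <- selectCutoffCV("xgb", tab, yp, cutoffConfig(seed = 5))
  expect_lte(cvp$gamma, 0.25)

  expect_error(selectCutoffCV("xgb", tab[1:12, ], y[1:12], cutoffConfig()),
               "n_folds")
})

test_that("confusion metrics reproduce hand counts and identities", {
  # an 8-row worked example, counted by hand: cutoff 0.5
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0) == 1
  scores <- c(.9, .8, .4, .6, .3, .7, .2, .1)
  rep8 <- confusionMetrics(labels, scores, 0.5)
  expect_identical(confusionCounts(rep8),
                   c(TP = 3L, FP = 1L, TN = 3L, FN = 1L))
  expect_equal(rep8@accuracy, 6 / 8)
  expect_equal(rep8@f1, 2 * 3 / (2 * 3 + 1 + 1))
  expect_equal(rep8@youden, 3 / 4 + 3 / 4 - 1)

  perfect <- confusionMetrics(labels, as.numeric(labels), 0.5)
  expect_equal(perfect@accuracy, 1)
  expect_equal(perfect@f1, 1)
  expect_equal(perfect@youden, 1)

  expect_error(confusionMetrics(logical(0), numeric(0)), "empty")
})

test_that("AUC equals pairwise concordance and is rank-invariant", {
  expect_equal(rocAUC(c(F, F, T, T), c(.1, .2, .8, .9)), 1)
  expect_equal(rocAUC(c(F, F, T, T), c(.9, .8, .2, .1)), 0)
  set.seed(23)
  for (rep in 1:6) {
    labels <- rbinom(30, 1, 0.5) == 1
    if (length(unique(labels)) < 2) next
    scores <- round(runif(30), 1)
    # O(n^2) concordance oracle with ties counted 1/2
    pos <- scores[labels]; neg <- scores[!labels]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(rocAUC(labels, scores), mean(cmp), tolerance = 1e-12)
    # invariance under a strictly monotone transform
    expect_equal(rocAUC(labels, scores), rocAUC(labels, qlogis(scores / 2 + 0.25)),
                 tolerance = 1e-12)
  }
})

test_that("the chi-square df = 2 closed form is exact", {
  expect_equal(chi2df2P(0), 1)
  expect_equal(chi2df2P(11.878), exp(-11.878 / 2))
  for (x in c(0.3, 2.9, 11.878, 22.90, 40)) {
    expect_equal(chi2df2P(x), pchisq(x, df = 2, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  expect_equal(signif(chi2df2P(22.90), 3), 1.06e-05)
})

test_that("univariate tests are routed by table shape and sparsity", {
  # materialize a labeled cohort with exact category counts
  mk <- function(yes1, no1, unk1, yes0, no0, unk0) {
    lvo <- rep(c(TRUE, FALSE), c(yes1 + no1 + unk1, yes0 + no0 + unk0))
    v <- c(rep(c("Yes", "No", NA), c(yes1, no1, unk1)),
           rep(c("Yes", "No", NA), c(yes0, no0, unk0)))
    data.frame(id = seq_along(lvo), lvo = lvo, v = v, stringsAsFactors = FALSE)
  }
  # balanced 2x2 -> p = 1
  bal <- tableOne(mk(30, 30, 0, 30, 30, 0))
  expect_equal(bal$p[bal$variable == "v"], 1)
  expect_match(bal$test[bal$variable == "v"], "yates")

  # 3-level table routed to the df = 2 engine
  t3 <- tableOne(mk(41, 11, 78, 44, 53, 73))
  expect_match(t3$test[t3$variable == "v"], "df2")

  # sparse table routed to Fisher
  sp <- tableOne(mk(2, 58, 0, 1, 59, 0))
  expect_match(sp$test[sp$variable == "v"], "fisher")

  # continuous column routed to the pooled t-test
  set.seed(3)
  d <- data.frame(id = 1:40, lvo = rep(c(TRUE, FALSE), 20), x = rnorm(40))
  tt <- tableOne(d)
  expect_match(tt$test[tt$variable == "x"], "student")
  ref <- t.test(d$x[d$lvo], d$x[!d$lvo], var.equal = TRUE)$p.value
  expect_equal(tt$p[tt$variable == "x"], ref, tolerance = 1e-12)

  expect_error(tableOne(data.frame(id = 1:3, lvo = c(TRUE, TRUE, TRUE), x = 1:3)),
               "both classes")
})
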