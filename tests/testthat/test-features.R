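test_that("t screening matches the textbook pooled-variance computation", {
  x1 <- c(4.1, 5.2, 3.9, 4.8); x0 <- c(2.0, 2.6, 1.7, 2.9)
  X <- matrix(c(x1, x0, rnorm(8)), ncol = 2)
  labels <- rep(c(TRUE, FALSE), each = 4)
  res <- ttestScreen(X, labels, top_k = 2)
  ref <- t.test(x1, x0, var.equal = TRUE)$p.value
  expect_equal(res$p[1], ref, tolerance = 1e-12)
})

test_that("screening ranks separation above constants and noise", {
  set.seed(5)
  n <- 200
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  X <- cbind(const = rep(2, n),
             signal = as.numeric(labels) + rnorm(n, 0, 0.1),
             noise = rnorm(n))
  res <- ttestScreen(X, labels, top_k = 2)
  expect_equal(res$p[[1]], 1)            # constant channel
  expect_equal(res$indices[1], 2L)       # signal ranked first
  expect_false(1L %in% res$indices)      # constant never beats separation

  # permutation invariance in patient order
  perm <- sample(n)
  res2 <- ttestScreen(X[perm, ], labels[perm], top_k = 2)
  expect_identical(res$indices, res2$indices)

  # ties in p break by channel index
  Xt <- cbind(X[, 2], X[, 2], X[, 3])
  res3 <- ttestScreen(Xt, labels, top_k = 2)
  expect_identical(res3$indices, c(1L, 2L))

  expect_error(ttestScreen(X, rep(TRUE, n)), "both classes")
})

test_that("level assembly nests the feature blocks deterministically", {
  coh <- generateCohort(cohortConfig(n_patients = 30, seed = 2))
  l1 <- assembleLevel(1, coh)
  l2 <- assembleLevel(2, coh)
  expect_true(all(names(l1) %in% names(l2)))
  expect_gt(ncol(l2), ncol(l1))
  expect_identical(rownames(l2), coh$id)

  deep <- matrix(rnorm(30 * 32), 30, 32, dimnames = list(coh$id, NULL))
  sel <- c(3L, 7L, 9L, 11L, 2L, 20L, 25L, 31L, 14L, 5L)
  l3 <- assembleLevel(3, coh, deep_features = deep, selected = sel)
  expect_equal(ncol(l3), ncol(l2) + 10)
  expect_identical(names(l3)[(ncol(l2) + 1):ncol(l3)], sprintf("f%04d", sel))
  expect_identical(sort(rownames(l3)), sort(coh$id))
  expect_false(any(duplicated(rownames(l3))))
  expect_error(assembleLevel(3, coh), "deep features")

  empty <- generateCohort(cohortConfig(n_patients = 0, seed = 1))
  e1 <- assembleLevel(1, empty)
  expect_equal(nrow(e1), 0)
  expect_identical(names(e1), names(l1))
})
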