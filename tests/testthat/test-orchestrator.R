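test_that("a single-cell run produces one valid report row", {
  cfg <- runConfig(n_patients = 80, n_train = 56, levels = 1L, families = "xgb",
                   seed = 3)
  res <- runPipeline(cfg)
  expect_equal(nrow(res$report), 1)
  expect_identical(res$report$family, "xgb")
  expect_identical(res$report$data, "Raw")
  rep1 <- res$metrics[["L1_xgb"]]
  expect_s4_class(rep1, "MetricsReport")
  expect_true(validObject(rep1))
  # the report row mirrors the MetricsReport
  expect_equal(res$report$youden, rep1@youden)
  expect_equal(res$report$auc, rep1@auc)
  # stratified split arithmetic
  expect_length(res$artifacts$split$train, 56)
  expect_length(res$artifacts$split$test, 24)
})

test_that("tabular levels run all families deterministically", {
  cfg <- runConfig(n_patients = 80, n_train = 56, levels = 1:2,
                   families = c("lr", "xgb"), seed = 9)
  r1 <- runPipeline(cfg)
  r2 <- runPipeline(cfg)
  expect_equal(r1$report, r2$report)
  expect_equal(nrow(r1$report), 4)           # 2 levels x 2 families
  expect_true(all(r1$report$auc >= 0 & r1$report$auc <= 1))
  expect_true(all(r1$report$cutoff > 0 & r1$report$cutoff < 1))
  # Youden identity holds on every cell
  expect_equal(r1$report$youden,
               r1$report$recall + r1$report$specificity - 1)
})
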