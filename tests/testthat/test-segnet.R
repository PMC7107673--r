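test_that("network shapes follow the configuration contract", {
  tiny <- segNetConfig("tiny")
  expect_equal(tiny$input_size / 2^tiny$depth, 4)        # 4 x 4 bottleneck
  full <- segNetConfig("full")
  expect_equal(full$input_size / 2^full$depth, 4)
  expect_equal(full$bottleneck_channels, 1024)

  cfg <- segNetConfig(profile = NULL, input_size = 8, depth = 1,
                      base_channels = 1, intensity_scale = 1)
  net <- buildSegNet(cfg, seed = 2)
  out <- predictSegNet(net, matrix(runif(64), 8, 8))
  expect_equal(dim(out), c(8, 8))
  expect_true(all(out > 0 & out < 1))

  expect_error(segNetConfig(profile = NULL, input_size = 50, depth = 3,
                            base_channels = 4), "divisible")
})

test_that("the feature head equals an exhaustive max over bottleneck maps", {
  cfg <- segNetConfig(profile = NULL, input_size = 16, depth = 2,
                      base_channels = 2, intensity_scale = 1)
  net <- buildSegNet(cfg, seed = 9)
  x <- matrix(runif(256), 16, 16)
  fw <- strokehier:::.segFwd(list(config = net@config, params = net@params),
                             x, cache = TRUE)
  rb <- fw$cache$bott_r                     # bottleneck maps, 4 x 4 x C
  oracle <- numeric(dim(rb)[3])
  for (ch in seq_len(dim(rb)[3])) {
    mx <- -Inf
    for (i in 1:4) for (j in 1:4) mx <- max(mx, rb[i, j, ch])
    oracle[ch] <- mx
  }
  expect_equal(segFeatureHead(net, x), oracle)
  expect_length(segFeatureHead(net, x), cfg$bottleneck_channels)
})

test_that("Tversky loss matches hand calculations and the Dice limit", {
  t1 <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_lt(tverskyLoss(t1, t1, 0.3, 0.7), 1e-6)
  expect_gt(tverskyLoss(1 - t1, t1, 0.3, 0.7), 1 - 1e-4)

  pred <- matrix(c(0.5, 0, 0.5, 0), 2, 2)  # row-major [0.5 0.5; 0 0]
  # hand expansion: TP = 0.5, FP = 0.5, FN = 0.5
  eps <- 1e-6
  hand <- 1 - (0.5 + eps) / (0.5 + 0.5 * 0.5 + 0.5 * 0.5 + eps)
  expect_equal(tverskyLoss(pred, t1, 0.5, 0.5), hand, tolerance = 1e-12)

  # spatial permutation symmetry
  set.seed(8)
  p <- matrix(runif(36), 6, 6); y <- matrix(rbinom(36, 1, .3), 6, 6)
  perm <- sample(36)
  expect_equal(tverskyLoss(p, y, 0.3, 0.7),
               tverskyLoss(matrix(p[perm], 6, 6), matrix(y[perm], 6, 6), 0.3, 0.7))

  # alpha = beta = 0.5 equals soft Dice
  tp <- sum(p * y); fp <- sum(p * (1 - y)); fn <- sum((1 - p) * y)
  soft_dice_loss <- 1 - (2 * tp + 2 * eps) / (2 * tp + fp + fn + 2 * eps)
  expect_equal(tverskyLoss(p, y, 0.5, 0.5), soft_dice_loss, tolerance = 1e-9)

  expect_error(tverskyLoss(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("hard-negative mining keeps positives and the hardest negatives", {
  losses <- c(0.9, seq(0.05, 0.5, length.out = 10))
  is_pos <- c(TRUE, rep(FALSE, 10))
  kept <- mineHardNegatives(losses, is_pos, ratio = 3)
  expect_length(kept, 4)
  expect_true(1 %in% kept)
  neg_kept <- setdiff(kept, 1)
  neg_drop <- setdiff(2:11, neg_kept)
  expect_true(min(losses[neg_kept]) >= max(losses[neg_drop]))

  all_pos <- mineHardNegatives(c(.2, .3), c(TRUE, TRUE), ratio = 3)
  expect_setequal(all_pos, 1:2)
})

test_that("training is seeded, order-invariant and refuses empty truth", {
  cfg <- segNetConfig(profile = NULL, input_size = 16, depth = 2,
                      base_channels = 2, intensity_scale = 80)
  pool <- fxDotPool(16L, pos_every = 4L, n = 16L)
  tc <- segTrainConfig(epochs = 3, seed = 12, batch_size = 8)
  n1 <- trainSegmenter(pool$patches, pool$masks, cfg, tc)
  n2 <- trainSegmenter(pool$patches, pool$masks, cfg, tc)
  expect_identical(n1@params, n2@params)
  expect_identical(tail(n1@state$history, 1), tail(n2@state$history, 1))

  perm <- c(9:16, 1:8)
  n3 <- trainSegmenter(pool$patches[perm], pool$masks[perm], cfg, tc)
  expect_identical(n1@params, n3@params)

  zero_masks <- lapply(pool$masks, function(m) m * 0L)
  expect_error(trainSegmenter(pool$patches, zero_masks, cfg, tc), "no positive")
})

test_that("training loss decreases on a smoothed window", {
  cfg <- segNetConfig(profile = NULL, input_size = 16, depth = 2,
                      base_channels = 4, intensity_scale = 80)
  pool <- fxDotPool(24L, pos_every = 2L, n = 16L)
  net <- trainSegmenter(pool$patches, pool$masks, cfg,
                        segTrainConfig(epochs = 12, seed = 3, batch_size = 8))
  h <- net@state$history
  expect_lt(mean(tail(h, 4)), mean(head(h, 4)))
})

test_that("representative slice selection follows the area rule", {
  expect_equal(selectRepresentativeSlice(rep(0, 6)), 3L)
  expect_equal(selectRepresentativeSlice(c(0, 5, 0, 9, 0, 0)), 4L)
  expect_equal(selectRepresentativeSlice(c(7, 7, 0, 0, 0, 0)), 1L)
})

test_that("feature extraction pools both hemispheres and needs a trained net", {
  net <- fxTinyNet()
  lesion <- fxDotPatch(TRUE, seed = 9001, n = 128)
  blank <- fxDotPatch(FALSE, seed = 9002, n = 128)
  pts <- c(list(lesion$patch), lapply(2:12, function(i) blank$patch))
  stack <- fxStack(pts, id = "HEMI")
  f1 <- extractDeepFeatures(net, stack)
  expect_s4_class(f1, "DeepFeatures")
  expect_length(featureValues(f1), segNetConfig("tiny")$bottleneck_channels)

  # swapping the hemisphere patches slice-by-slice leaves the vector intact
  swap <- pts[c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9, 12, 11)]
  f2 <- extractDeepFeatures(net, fxStack(swap, id = "HEMI"))
  expect_equal(featureValues(f1), featureValues(f2))

  # all-zero patches reduce to the zero-input response of the feature head
  zstack <- fxStack(lapply(1:12, function(i) matrix(0, 128, 128)), id = "Z")
  fz <- extractDeepFeatures(net, zstack)
  zref <- segFeatureHead(net, matrix(0, 128, 128))
  expect_equal(featureValues(fz), pmax(zref, zref))
  expect_equal(sourceSlice(fz), 3L)   # nothing predicted -> middle slice

  raw <- buildSegNet(segNetConfig("tiny"))
  expect_error(extractDeepFeatures(raw, stack), "untrained")
})
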