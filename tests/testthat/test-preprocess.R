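test_that("brain extraction recovers the head interior and excludes bone", {
  fx <- fxSignedStudy()
  pc <- preprocessConfig()
  mask <- extractBrain(fx$study@volume, pc)
  tpl <- strokehier:::.headTemplate(fx$config)
  vox <- voxels(fx$study)
  for (s in c(1, 5, 10)) {
    m <- mask[, , s] > 0
    dice <- 2 * sum(m & tpl$brain) / (sum(m) + sum(tpl$brain))
    expect_gte(dice, 0.95)
    expect_equal(sum(m & vox[, , s] >= pc$skull_threshold), 0)
  }

  air <- new("CTVolume", voxels = array(0, c(512, 512, 10)), pixelMm = 0.426,
             sliceMm = 5, id = "air")
  expect_error(extractBrain(air, pc), "no brain found")
})

test_that("rigid registration is a fixed point on symmetric volumes and inverts known rotations", {
  fx <- fxSignedStudy()
  pc <- preprocessConfig()
  reg <- registerAxial(fx$study@volume, pc)
  tf <- attr(reg, "transform")
  expect_lt(abs(tf$angle), 1)
  expect_lt(max(abs(tf$shift)), 1)

  rot <- generatePhantom(phantomConfig(rotation_deg = 7, seed = 55L),
                         label_lvo = TRUE, seed = 55L, id = "ROT")
  reg2 <- registerAxial(rot@volume, pc)
  tf2 <- attr(reg2, "transform")
  expect_lt(abs(tf2$angle - (-7)), 0.5)
})

test_that("registration never decreases the symmetry score", {
  pc <- preprocessConfig()
  mid <- pc$slice_range[ceiling(length(pc$slice_range) / 2)]
  for (s in 1:8) {
    ang <- runif(1, -10, 10)
    ph <- generatePhantom(phantomConfig(rotation_deg = ang, seed = 700L + s),
                          label_lvo = s %% 2 == 0, seed = 700L + s)
    before <- strokehier:::.symmetryScore(voxels(ph)[, , mid])
    reg <- suppressWarnings(registerAxial(ph@volume, pc))
    after <- strokehier:::.symmetryScore(voxels(reg)[, , mid])
    expect_gte(after, before - 1e-9)
  }
})

test_that("median filtering and windowing follow the exact contract", {
  pc <- preprocessConfig()
  const <- matrix(50, 16, 16)
  expect_equal(denoiseWindow(const, pc), const)

  # window routing after an identity median (constant blocks)
  m <- matrix(60, 9, 9); m[1:3, ] <- 150; m[7:9, ] <- 10
  out <- denoiseWindow(m, pc)
  expect_true(all(out[1, ] == 0))    # skull-bright zeroed
  expect_true(all(out[9, ] == 0))    # CSF-dark zeroed
  expect_true(all(out[5, ] == 60))   # clot-like intensity preserved

  # brute-force ordered-statistic reference on a random slice
  set.seed(31)
  x <- matrix(runif(32 * 32, 0, 120), 32, 32)
  pad <- x[pmin(pmax(0:33, 1), 32), pmin(pmax(0:33, 1), 32)]
  ref <- matrix(0, 32, 32)
  for (i in 1:32) for (j in 1:32) ref[i, j] <- median(pad[i:(i + 2), j:(j + 2)])
  ref[ref < 20 | ref > 80] <- 0
  expect_equal(denoiseWindow(x, pc), ref)

  # windowing is idempotent
  once <- denoiseWindow(x, pc)
  again <- once
  again[again < pc$window_low | again > pc$window_high] <- 0
  expect_identical(again, once)
})

test_that("ROI cropping yields the 12 mirror-consistent patches", {
  fx <- fxSignedStudy()
  pc <- preprocessConfig()
  vol <- denoiseWindow(registerAxial(fx$study@volume, pc), pc)
  stack <- cropROI(vol, pc)
  expect_s4_class(stack, "ROIStack")
  expect_length(patches(stack), 12)
  expect_true(all(vapply(patches(stack), function(p) all(dim(p) == 128), logical(1))))
  expect_true(all(unlist(patches(stack)) >= 0 & unlist(patches(stack)) <= pc$window_high))

  zero <- new("CTVolume", voxels = array(0, c(512, 512, 10)), pixelMm = .426,
              sliceMm = 5, id = "z")
  zstack <- cropROI(zero, pc)
  expect_true(all(vapply(patches(zstack), function(p) all(p == 0), logical(1))))

  short <- new("CTVolume", voxels = array(0, c(512, 512, 10)), pixelMm = .426,
               sliceMm = 5, id = "s")
  expect_error(cropROI(short, preprocessConfig(slice_range = 8:13)), "insufficient")

  # mirroring the volume across the mid-row axis swaps and mirrors patches
  mvox <- voxels(vol)[512:1, , ]
  mirr <- new("CTVolume", voxels = mvox, pixelMm = .426, sliceMm = 5, id = "m")
  mstack <- cropROI(mirr, pc)
  p <- patches(stack); pm <- patches(mstack)
  for (k in seq(1, 11, by = 2)) {
    expect_equal(pm[[k]], p[[k + 1]][128:1, ])      # A of mirror = flipped B
    expect_equal(pm[[k + 1]], p[[k]][128:1, ])      # B of mirror = flipped A
  }
})

test_that("the lesion survives preprocessing inside exactly one patch", {
  fx <- fxSignedStudy()
  masks <- fx$pre$masks
  nz <- vapply(masks, function(m) sum(m) > 0, logical(1))
  expect_equal(sum(nz), 1L)
  expect_equal(sum(vapply(masks, sum, numeric(1))), sum(truthMask(fx$study)))
  # the lesion patch is bright where the mask is set (windowed intensities)
  k <- which(nz)
  patch <- patches(fx$pre$stack)[[k]]
  expect_true(all(patch[masks[[k]] == 1] > 20 & patch[masks[[k]] == 1] <= 80))
})
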