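test_that("cohort generation is seeded, sized and class-balanced", {
  cfg <- cohortConfig(n_patients = 300, seed = 11)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 300)
  # binomial tolerance around 0.433 * 300 = 130 (about 4 SD)
  expect_lt(abs(sum(a$lvo) - 130), 35)

  empty <- generateCohort(cohortConfig(n_patients = 0, seed = 1))
  expect_equal(nrow(empty), 0)
  expect_true(all(c("id", "lvo", "age", "gcs", "smoker") %in% names(empty)))

  bad <- defaultFeatureSpec()
  bad$gender$p_lvo <- c(0.5, 0.6)
  expect_error(cohortConfig(feature_spec = bad), "sum")
})

test_that("class-conditional marginals are recovered at n = 5000", {
  coh <- generateCohort(cohortConfig(n_patients = 5000, seed = 42))
  af_yes <- coh$atrial_fibrillation == "Yes" & !is.na(coh$atrial_fibrillation)
  # direct counting oracle against the configured conditionals
  expect_lt(abs(mean(af_yes[coh$lvo]) - 48 / 130), 0.02)
  expect_lt(abs(mean(af_yes[!coh$lvo]) - 32 / 170), 0.02)
  expect_lt(abs(mean(is.na(coh$smoker[coh$lvo])) - 53 / 130), 0.02)
  expect_lt(abs(mean(is.na(coh$smoker[!coh$lvo])) - 53 / 170), 0.02)
  expect_lt(abs(mean(coh$age[coh$lvo]) - 79.69), 0.6)
  expect_lt(abs(mean(coh$age[!coh$lvo]) - 73.19), 0.6)
})

test_that("records are internally consistent", {
  coh <- generateCohort(cohortConfig(n_patients = 2000, seed = 7))
  sub_ok <- !is.na(coh$gcs_eye)
  expect_true(all(coh$gcs[sub_ok] ==
                  coh$gcs_eye[sub_ok] + coh$gcs_verbal[sub_ok] + coh$gcs_motor[sub_ok]))
  expect_true(all(coh$gcs >= 3 & coh$gcs <= 15, na.rm = TRUE))
  expect_true(all(coh$gcs_eye %in% 1:4 | is.na(coh$gcs_eye)))
  expect_true(all(coh$gcs_verbal %in% 1:5 | is.na(coh$gcs_verbal)))
  expect_true(all(coh$gcs_motor %in% 1:6 | is.na(coh$gcs_motor)))
  expect_true(all(coh$dbp > 0, na.rm = TRUE))
  expect_true(all(coh$sbp > 0, na.rm = TRUE))
  # any-side weakness agrees with the side indicators
  obs <- !is.na(coh$facial_weakness)
  any_side <- coh$left_facial_weakness == "Yes" | coh$right_facial_weakness == "Yes"
  expect_identical(coh$facial_weakness[obs] == "Yes", any_side[obs])
  # current/ex smoker implies smoker
  obs <- !is.na(coh$smoker)
  expect_true(all(coh$smoker[obs & (coh$current_smoker == "Yes" | coh$ex_smoker == "Yes")] == "Yes"))
})

test_that("phantoms carry the configured sign structure and intensities", {
  fx <- fxSignedStudy()
  expect_true(hasSign(fx$study))
  expect_gt(sum(truthMask(fx$study)), 0)

  vox <- voxels(fx$study)
  lesion_vals <- vox[truthMask(fx$study) == 1]
  expect_true(all(lesion_vals > 20 & lesion_vals <= 80))
  # distractors and skull are the only supra-window voxels, all far above it
  expect_true(all(vox[vox > 80] >= 120))

  # conditional sign probability follows the configured counts (68 of the 74
  # sign-positive patients have LVO): P(LVO | sign) = 68/74 = 0.919
  p_sign_lvo <- 68 / 130; p_sign_nolvo <- 6 / 170; prev <- 0.433
  p_lvo_sign <- p_sign_lvo * prev / (p_sign_lvo * prev + p_sign_nolvo * (1 - prev))
  expect_equal(round(p_lvo_sign, 3), round(68 / 74, 3), tolerance = 1e-8)

  # empirical 2x2 over simulated patients at the default rates
  cfg <- phantomConfig(seed = 303L)
  lab <- rep(c(TRUE, FALSE), c(43, 57))  # 43.3% prevalence, 100 patients
  sgn <- vapply(seq_along(lab), function(i)
    hasSign(generatePhantom(cfg, lab[i], seed = 4000 + i)), logical(1))
  # sign rate P(sign) = 74/300 = 0.247; allow 4 SD binomial noise
  expect_lt(abs(mean(sgn) - 74 / 300), 4 * sqrt(0.247 * 0.753 / 100))
  expect_gt(mean(lab[sgn]), 0.75)  # sign is highly specific for LVO

  expect_error(generatePhantom(phantomConfig(n_slices = 10)[c()], TRUE), "phantomConfig")
  expect_error(phantomConfig(n_slices = 5), "n_slices")
})

test_that("forced-sign phantoms always carry a lesion in the ROI zone", {
  cfg <- phantomConfig(p_sign_given_lvo = 1, seed = 77L)
  for (s in 1:3) {
    ph <- generatePhantom(cfg, label_lvo = TRUE, seed = 600 + s)
    expect_true(hasSign(ph))
    idx <- which(truthMask(ph) == 1, arr.ind = TRUE)
    # every lesion voxel inside one of the two ROI boxes (rows 129:256 or
    # 257:384, cols 213:340, slices 4..9 in 1-based coordinates)
    in_a <- idx[, 1] >= 129 & idx[, 1] <= 256
    in_b <- idx[, 1] >= 257 & idx[, 1] <= 384
    expect_true(all(in_a | in_b))
    expect_true(all(in_a) || all(in_b))  # exactly one hemisphere
    expect_true(all(idx[, 2] >= 213 & idx[, 2] <= 340))
    expect_true(all(idx[, 3] >= 4 & idx[, 3] <= 9))
  }
})

test_that("cohort CSV and phantom NIfTI round-trip", {
  coh <- generateCohort(cohortConfig(n_patients = 40, seed = 13))
  f <- tempfile(fileext = ".csv")
  writeCohortCSV(coh, f)
  back <- readCohortCSV(f)
  expect_identical(back$id, coh$id)
  expect_identical(back$lvo, coh$lvo)
  expect_identical(back$smoker, coh$smoker)       # NA round-trips via "Unknown"
  expect_equal(back$age, coh$age, tolerance = 1e-9)
  expect_identical(levelColumns(back, "1"), levelColumns(coh, "1"))

  fx <- fxSignedStudy()
  d <- file.path(tempdir(), "nifti-rt")
  writePhantomNIfTI(fx$study, d, id = "RT01")
  vol <- readCTVolume(file.path(d, "RT01_vol.nii.gz"))
  expect_s4_class(vol, "CTVolume")
  expect_equal(dim(voxels(vol)), dim(voxels(fx$study)))
  expect_equal(max(abs(voxels(vol) - voxels(fx$study))), 0, tolerance = 1e-4)
  mf <- read.csv(file.path(d, "manifest.csv"))
  expect_identical(mf$id[1], "RT01")
  expect_true(mf$has_sign[1])
})
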