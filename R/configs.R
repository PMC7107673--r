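# Configuration constructors. Each returns a validated plain list; keeping
# configs as lists (rather than S4) mirrors how fit functions in this tier
# take tuning arguments, while still centralizing validation.

#' Derive a named sub-seed from a master seed
#'
#' Deterministically maps a master seed and a stream name to a 32-bit
#' sub-seed (Lehmer-style hash), so cohort, phantom and training randomness
#' can be re-run independently of one another.
#'
#' @param seed integer master seed.
#' @param name character stream name.
#' @return an integer seed below 2^31.
#' @export
substreamSeed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131L)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Cohort generator configuration
#'
#' Defines the synthetic tabular cohort: sample size, LVO prevalence, and a
#' per-variable marginal specification (class-conditional means/CIs for
#' continuous variables, class-conditional level probabilities -- including
#' an Unknown/missing mass -- for categorical ones). The default
#' `feature_spec` is [defaultFeatureSpec()], which encodes the marginal
#' structure of a 300-patient stroke cohort with 43.3% LVO prevalence.
#'
#' @param n_patients number of records to generate.
#' @param lvo_prevalence P(LVO); default 0.433.
#' @param feature_spec per-variable marginal description.
#' @param seed integer seed.
#' @return a `cohortConfig` list.
#' @export
cohortConfig <- function(n_patients = 300L, lvo_prevalence = 0.433,
                         feature_spec = defaultFeatureSpec(), seed = 1L) {
  if (n_patients < 0) stop("n_patients must be >= 0")
  if (lvo_prevalence < 0 || lvo_prevalence > 1)
    stop("lvo_prevalence must lie in [0,1]")
  for (nm in names(feature_spec)) {
    fs <- feature_spec[[nm]]
    if (fs$type == "categorical") {
      for (cl in c("p_lvo", "p_nolvo")) {
        s <- sum(fs[[cl]])
        if (abs(s - 1) > 1e-9)
          stop(sprintf("probabilities for %s (%s) sum to %.12f, not 1", nm, cl, s))
        if (any(fs[[cl]] < 0)) stop(sprintf("negative probability mass in %s", nm))
      }
    }
  }
  structure(list(n_patients = as.integer(n_patients),
                 lvo_prevalence = lvo_prevalence,
                 feature_spec = feature_spec, seed = as.integer(seed)),
            class = "cohortConfig")
}

# Back-solve a class SD from a printed 95% CI of the mean: hw = t* sd/sqrt(n).
.sdFromCI <- function(ci, n) (ci[2] - ci[1]) / 2 * sqrt(n) / qt(0.975, n - 1)

#' Default cohort marginal specification
#'
#' Class-conditional marginals of the emulated stroke cohort (130 LVO / 170
#' non-LVO). Continuous variables carry per-class means with 95% CIs (the SD
#' is back-solved from the CI at the observed count); categorical variables
#' carry per-class level probabilities with `"Unknown"` as an explicit level
#' where records are incomplete. Structurally dependent variables are listed
#' as composite blocks so sampling keeps records internally consistent:
#' limb/facial weakness are drawn as side patterns, smoking status as a
#' never/current/ex trichotomy, and GCS subscales are drawn first with the
#' total derived as their sum.
#'
#' @return a named list of per-variable marginal descriptions.
#' @export
defaultFeatureSpec <- function() {
  cat2 <- function(level, yes_l, yes_n, n_l = 130, n_n = 170, levels = c("Yes", "No")) {
    list(type = "categorical", level = level, levels = levels,
         p_lvo = c(yes_l, n_l - yes_l) / n_l, p_nolvo = c(yes_n, n_n - yes_n) / n_n)
  }
  # composite block: side-specific weakness pattern (both/left/right/none)
  sidePattern <- function(level, counts_l, counts_n, unknown_l = 0, unknown_n = 0) {
    list(type = "side_pattern", level = level,
         levels = c("Both", "Left", "Right", "None"),
         p_lvo = counts_l / sum(counts_l), p_nolvo = counts_n / sum(counts_n),
         p_unknown = c(lvo = unknown_l / 130, nolvo = unknown_n / 170))
  }
  cont <- function(level, mean_l, ci_l, mean_n, ci_n, na_l = 0, na_n = 0,
                   lower = -Inf, upper = Inf, integer = FALSE) {
    n_l <- 130 - na_l; n_n <- 170 - na_n
    list(type = "continuous", level = level,
         mean = c(lvo = mean_l, nolvo = mean_n),
         sd = c(lvo = .sdFromCI(ci_l, n_l), nolvo = .sdFromCI(ci_n, n_n)),
         p_missing = c(lvo = na_l / 130, nolvo = na_n / 170),
         lower = lower, upper = upper, integer = integer)
  }
  list(
    age = cont("1", 79.69, c(77.55, 81.84), 73.19, c(71.15, 75.24),
               lower = 18, upper = 110),
    gender = list(type = "categorical", level = "1", levels = c("Female", "Male"),
                  p_lvo = c(84, 46) / 130, p_nolvo = c(76, 94) / 170),
    # limb: 129/130 LVO and 126/170 non-LVO have any limb weakness;
    # side counts (L 59/63, R 73/70) overlap, giving 3 resp. 7 bilateral
    limb_weakness = sidePattern("1", c(3, 56, 70, 1), c(7, 56, 63, 44)),
    # facial: Unknown mass 78/73; among observed, Yes splits into exactly
    # one side (19+22 = 41 LVO, 25+19 = 44 non-LVO)
    facial_weakness = sidePattern("1", c(0, 19, 22, 11), c(0, 25, 19, 53),
                                  unknown_l = 78, unknown_n = 73),
    speech_deficit = cat2("1", 62, 72),
    gcs = list(
      type = "gcs", level = "2",
      # subscale means/CIs; totals derived as eye+verbal+motor
      eye = list(mean = c(3.18, 3.83), ci_l = c(2.96, 3.41), ci_n = c(3.72, 3.93), range = c(1, 4)),
      verbal = list(mean = c(2.44, 4.25), ci_l = c(2.14, 2.74), ci_n = c(4.02, 4.48), range = c(1, 5)),
      motor = list(mean = c(5.16, 5.70), ci_l = c(4.96, 5.36), ci_n = c(5.56, 5.85), range = c(1, 6)),
      n_obs = c(lvo = 98, nolvo = 145),
      # subscales unrecorded for 32/130 resp. 25/170; among those, the total
      # itself is still recorded unless in the 9/130 resp. 15/170 core-missing set
      p_sub_missing = c(lvo = 32 / 130, nolvo = 25 / 170),
      p_total_missing_given_sub = c(lvo = 9 / 32, nolvo = 15 / 25)),
    bp = list(
      type = "bp", level = "2",
      dbp = list(mean = c(84.50, 83.90), ci_l = c(80.71, 88.29), ci_n = c(80.99, 86.82)),
      sbp = list(mean = c(154.82, 162.40), ci_l = c(148.62, 161.02), ci_n = c(157.46, 167.34)),
      n_obs = c(lvo = 74, nolvo = 92),
      p_missing = c(lvo = 56 / 130, nolvo = 78 / 170)),
    diabetes = cat2("2", 30, 45),
    hypertension = cat2("2", 89, 118),
    # smoking: never/current/ex trichotomy among observed; shared Unknown mask
    smoking = list(type = "smoking", level = "2",
                   p_lvo = c(never = 62, current = 8, ex = 7) / 77,
                   p_nolvo = c(never = 70, current = 22, ex = 25) / 117,
                   p_unknown = c(lvo = 53 / 130, nolvo = 53 / 170)),
    atherosclerosis = cat2("2", 3, 6, levels = c("Yes", "Unknown")),
    atrial_fibrillation = cat2("2", 48, 32, levels = c("Yes", "Unknown")),
    cardioembolism = cat2("2", 8, 2, levels = c("Yes", "Unknown")),
    valvular_heart_disease = cat2("2", 61, 86, levels = c("Yes", "Unknown"))
  )
}

#' Phantom generator configuration
#'
#' Geometry and intensity model for the pseudo-CT head phantom: an
#' elliptical brain of soft-tissue intensity inside a bright skull ring,
#' with an optional hyperdense MCA-sign dot planted in a proximal-Sylvian
#' zone of one hemisphere, plus calcification-like distractors. Lesion
#' intensities must survive the \[20, 80\] preprocessing window; skull and
#' distractor intensities must not.
#'
#' @param n_slices slices per volume (>= 10).
#' @param shape in-plane size (fixed at 512).
#' @param pixel_mm,slice_mm voxel spacing in millimetres.
#' @param background_intensity soft-tissue HU-like level.
#' @param lesion_intensity_range interval within (40, 80] for the MCA dot.
#' @param skull_intensity skull ring level (> 100).
#' @param distractor_rate probability of a calcification-like distractor per
#'   candidate slice.
#' @param p_sign_given_lvo,p_sign_given_nolvo class-conditional probability
#'   of carrying the hyperdense MCA sign (defaults 68/130 and 6/170).
#' @param noise_sd Gaussian texture SD inside the brain.
#' @param rotation_deg,shift_px optional in-plane rigid misalignment applied
#'   to the whole study (default none), used to exercise registration.
#' @param seed integer seed.
#' @return a `phantomConfig` list.
#' @export
phantomConfig <- function(n_slices = 10L, shape = 512L, pixel_mm = 0.426,
                          slice_mm = 5.0, background_intensity = 30,
                          lesion_intensity_range = c(45, 75),
                          skull_intensity = 150, distractor_rate = 0.5,
                          p_sign_given_lvo = 68 / 130,
                          p_sign_given_nolvo = 6 / 170,
                          noise_sd = 1.5, rotation_deg = 0, shift_px = c(0, 0),
                          seed = 1L) {
  if (n_slices < 10) stop("n_slices must be >= 10")
  if (shape != 512L) stop("in-plane shape is fixed at 512")
  if (lesion_intensity_range[1] <= 40 || lesion_intensity_range[2] > 80)
    stop("lesion intensities must lie within (40, 80]")
  if (skull_intensity <= 100) stop("skull intensity must exceed 100")
  for (p in c(p_sign_given_lvo, p_sign_given_nolvo, distractor_rate))
    if (p < 0 || p > 1) stop("probabilities must lie in [0,1]")
  structure(list(n_slices = as.integer(n_slices), shape = as.integer(shape),
                 pixel_mm = pixel_mm, slice_mm = slice_mm,
                 background_intensity = background_intensity,
                 lesion_intensity_range = lesion_intensity_range,
                 skull_intensity = skull_intensity,
                 distractor_rate = distractor_rate,
                 p_sign_given_lvo = p_sign_given_lvo,
                 p_sign_given_nolvo = p_sign_given_nolvo,
                 noise_sd = noise_sd, rotation_deg = rotation_deg,
                 shift_px = shift_px, seed = as.integer(seed)),
            class = "phantomConfig")
}

#' Preprocessing configuration
#'
#' The four-step NCCT pipeline: brain extraction, in-plane rigid
#' registration to bilateral symmetry, median filtering with intensity
#' windowing to \[20, 80\], and extraction of two mirror-image 128 x 128
#' bounding boxes over six candidate slices. Box coordinates follow the
#' 0-based half-open convention `[128:256, 212:340]` / `[256:384, 212:340]`
#' (rows, cols) on the 512 x 512 grid.
#'
#' @param window_low,window_high intensity window bounds; voxels outside are
#'   zeroed.
#' @param median_kernel odd kernel size for the per-slice median filter.
#' @param slice_range 1-based inclusive candidate slice indices.
#' @param box_a,box_b lists with 0-based half-open `rows`/`cols` bounds.
#' @param skull_threshold intensity above which a voxel is treated as bone
#'   during brain extraction.
#' @param closing_radius morphological closing radius (pixels) for the brain
#'   mask.
#' @param angle_grid rotation candidates (degrees) for registration.
#' @return a `preprocessConfig` list.
#' @export
preprocessConfig <- function(window_low = 20, window_high = 80,
                             median_kernel = 3L, slice_range = 4:9,
                             box_a = list(rows = c(128L, 256L), cols = c(212L, 340L)),
                             box_b = list(rows = c(256L, 384L), cols = c(212L, 340L)),
                             skull_threshold = 100, closing_radius = 2L,
                             angle_grid = seq(-15, 15, by = 0.5)) {
  if (window_low >= window_high) stop("window_low must be < window_high")
  if (median_kernel %% 2 != 1) stop("median_kernel must be odd")
  for (b in list(box_a, box_b)) {
    if (diff(b$rows) != 128L || diff(b$cols) != 128L)
      stop("bounding boxes must be 128 x 128")
  }
  # mirror-image check across the mid-row axis (row r <-> 512 - r, half-open)
  if (!(box_a$rows[1] + box_b$rows[2] == 512L && box_a$rows[2] + box_b$rows[1] == 512L &&
        identical(box_a$cols, box_b$cols)))
    stop("box_a and box_b must be mirror images across the mid-axis")
  structure(list(window_low = window_low, window_high = window_high,
                 median_kernel = as.integer(median_kernel),
                 slice_range = as.integer(slice_range), box_a = box_a, box_b = box_b,
                 skull_threshold = skull_threshold,
                 closing_radius = as.integer(closing_radius),
                 angle_grid = angle_grid),
            class = "preprocessConfig")
}

#' Segmentation network configuration
#'
#' Encoder-decoder FCN with 3x3 convolutions (stride 1, same padding), ReLU
#' activations, 2x2 max pooling, nearest-neighbour upsampling with encoder
#' skip connections, and a global-max-pool feature head over the bottleneck.
#' Channels double per stage; the bottleneck spatial size is
#' `input_size / 2^depth` (4 x 4 at both shipped profiles).
#'
#' The `"full"` profile (depth 5, base 32) keeps the complete 1024-channel
#' bottleneck of the original design; the `"tiny"` profile (depth 4, base 8,
#' 64 x 64 centre crop, 128-channel bottleneck) is the desk-scale default
#' used for end-to-end runs.
#'
#' @param profile `"tiny"` or `"full"`, or NULL to pass sizes explicitly.
#' @param input_size square input side; must be divisible by `2^depth`.
#' @param depth number of pooling stages.
#' @param base_channels channels at the first stage.
#' @param bottleneck_channels channels of the bottleneck maps (defaults to
#'   `base_channels * 2^depth`).
#' @param intensity_scale divisor mapping windowed intensities into \[0,1\].
#' @return a `segNetConfig` list.
#' @export
segNetConfig <- function(profile = "tiny", input_size = NULL, depth = NULL,
                         base_channels = NULL, bottleneck_channels = NULL,
                         intensity_scale = 80) {
  if (!is.null(profile)) {
    preset <- switch(profile,
      tiny  = list(input_size = 64L, depth = 4L, base_channels = 8L),
      full  = list(input_size = 128L, depth = 5L, base_channels = 32L),
      stop("unknown profile: ", profile))
    if (is.null(input_size)) input_size <- preset$input_size
    if (is.null(depth)) depth <- preset$depth
    if (is.null(base_channels)) base_channels <- preset$base_channels
  }
  if (is.null(bottleneck_channels))
    bottleneck_channels <- base_channels * 2^depth
  if (input_size %% 2^depth != 0)
    stop("input_size must be divisible by 2^depth")
  structure(list(input_size = as.integer(input_size), depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 bottleneck_channels = as.integer(bottleneck_channels),
                 intensity_scale = intensity_scale),
            class = "segNetConfig")
}

#' Segmentation training configuration
#'
#' Adam with first-moment decay 0.9; Tversky loss with asymmetric
#' false-positive/false-negative weights (defaults 0.3/0.7, penalizing
#' missed lesion pixels harder, the recommended regime for small lesions);
#' epoch-level hard-negative mining keeping `hard_negative_ratio` negatives
#' per positive patch. The full-scale reference settings are 200 epochs at
#' learning rate 1e-5; the desk-scale defaults trade epochs for a larger
#' step size.
#'
#' @param epochs training epochs.
#' @param learning_rate Adam step size.
#' @param beta1 Adam first-moment decay ("momentum").
#' @param batch_size minibatch size.
#' @param tversky_alpha,tversky_beta false-positive / false-negative weights.
#' @param hard_negative_ratio negatives kept per positive patch each epoch.
#' @param seed integer seed.
#' @return a `segTrainConfig` list.
#' @export
segTrainConfig <- function(epochs = 25L, learning_rate = 3e-4, beta1 = 0.9,
                           batch_size = 16L, tversky_alpha = 0.3,
                           tversky_beta = 0.7, hard_negative_ratio = 3,
                           seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (tversky_alpha <= 0 || tversky_beta <= 0)
    stop("tversky_alpha and tversky_beta must be > 0")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 beta1 = beta1, batch_size = as.integer(batch_size),
                 tversky_alpha = tversky_alpha, tversky_beta = tversky_beta,
                 hard_negative_ratio = hard_negative_ratio,
                 seed = as.integer(seed)),
            class = "segTrainConfig")
}

#' Cutoff selection configuration
#'
#' @param n_folds stratified folds (default 10).
#' @param seed integer seed controlling fold assignment.
#' @return a `cutoffConfig` list.
#' @export
cutoffConfig <- function(n_folds = 10L, seed = 1L) {
  if (n_folds < 2) stop("n_folds must be >= 2")
  structure(list(n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "cutoffConfig")
}

#' End-to-end run configuration
#'
#' @param n_patients cohort size (train + test).
#' @param n_train training-split size; the split is stratified by LVO label.
#' @param levels subset of feature levels 1:3 to run.
#' @param families subset of `c("lr","rf","svm","xgb")`.
#' @param seed master seed; all stages derive named substreams from it.
#' @param profile segmentation profile passed to [segNetConfig()].
#' @param seg_epochs segmentation training epochs for the run.
#' @param seg_max_patients cap on training-split patients whose patches
#'   enter segmentation training (sign-positive patients are kept
#'   preferentially so the pool always contains lesions).
#' @param cohort_config,phantom_config,preprocess_config stage configs.
#' @return a `runConfig` list.
#' @export
runConfig <- function(n_patients = 300L, n_train = 200L, levels = 1:3,
                      families = c("lr", "rf", "svm", "xgb"), seed = 1L,
                      profile = "tiny", seg_epochs = 12L, seg_max_patients = 40L,
                      cohort_config = NULL, phantom_config = NULL,
                      preprocess_config = preprocessConfig()) {
  if (n_train >= n_patients) stop("n_train must be smaller than n_patients")
  if (!all(levels %in% 1:3)) stop("levels must be within 1:3")
  if (!all(families %in% c("lr", "rf", "svm", "xgb")))
    stop("unknown model family")
  if (is.null(cohort_config))
    cohort_config <- cohortConfig(n_patients = n_patients,
                                  seed = substreamSeed(seed, "cohort"))
  if (is.null(phantom_config))
    phantom_config <- phantomConfig(seed = substreamSeed(seed, "phantom"))
  structure(list(n_patients = as.integer(n_patients), n_train = as.integer(n_train),
                 levels = as.integer(levels), families = families,
                 seed = as.integer(seed), profile = profile,
                 seg_epochs = as.integer(seg_epochs),
                 seg_max_patients = as.integer(seg_max_patients),
                 cohort_config = cohort_config, phantom_config = phantom_config,
                 preprocess_config = preprocess_config),
            class = "runConfig")
}
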