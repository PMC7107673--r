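# Pseudo-CT phantom studies.
#
# Each study is a 512 x 512 x S volume: an elliptical "brain" of soft-tissue
# intensity (~30) with Gaussian texture, enclosed by a bright skull ring
# (> 100), surrounded by air (0). With class-conditional probability the
# study carries a hyperdense MCA sign: a small bright dot (intensity inside
# the (20, 80] preprocessing window) planted in a proximal-Sylvian zone --
# a fixed disc around one hemisphere's ROI-box centre -- on one candidate
# slice. Calcification-like distractor dots (intensity > 80, so they are
# wiped by windowing) mimic the bony and vascular mimics seen near the MCA.

.phantomEnv <- new.env(parent = emptyenv())

# Static head template (brain + skull, no noise) cached per geometry.
.headTemplate <- function(config) {
  key <- paste(config$shape, config$n_slices, config$background_intensity,
               config$skull_intensity, sep = "|")
  tpl <- .phantomEnv[[key]]
  if (!is.null(tpl)) return(tpl)
  n <- config$shape
  ctr <- (n + 1) / 2
  ar <- 210; ac <- 180  # brain semi-axes (rows span the left-right axis)
  r2 <- outer(((seq_len(n) - ctr) / ar)^2, ((seq_len(n) - ctr) / ac)^2, "+")
  brain <- r2 <= 1
  skull <- r2 > 1 & r2 <= 1.13
  slice <- matrix(0, n, n)
  slice[brain] <- config$background_intensity
  slice[skull] <- config$skull_intensity
  tpl <- list(slice = slice, brain = brain, ar = ar, ac = ac)
  .phantomEnv[[key]] <- tpl
  tpl
}

# ROI-box centres in 1-based (row, col) coordinates, matching the default
# 0-based boxes [128:256, 212:340] (hemisphere A) and [256:384, 212:340] (B).
.roiCenters <- function() {
  list(A = c(r = 192.5, c = 276.5), B = c(r = 320.5, c = 276.5))
}

.stampDisc <- function(slice, center, radius, value) {
  n <- nrow(slice)
  rr <- max(1, floor(center[1] - radius)):min(n, ceiling(center[1] + radius))
  cc <- max(1, floor(center[2] - radius)):min(n, ceiling(center[2] + radius))
  d2 <- outer((rr - center[1])^2, (cc - center[2])^2, "+")
  sel <- d2 <= radius^2
  sub <- slice[rr, cc]
  sub[sel] <- value
  slice[rr, cc] <- sub
  slice
}

#' Generate one pseudo-CT phantom study
#'
#' Builds the head volume for a patient with the given LVO label, draws the
#' hyperdense-sign indicator from the class-conditional probabilities in
#' `config`, and (when present) plants a 2-6 pixel-radius bright dot with
#' intensity in `lesion_intensity_range` inside the proximal-Sylvian zone
#' (a 30-pixel disc around one hemisphere's ROI-box centre) on one candidate
#' slice. The binary `truthMask` marks lesion voxels only. Deterministic
#' given `seed`.
#'
#' @param config a [phantomConfig()].
#' @param label_lvo logical LVO label of the patient.
#' @param seed integer seed for this study (defaults to `config$seed`).
#' @param id patient identifier stored on the volume.
#' @return a [PhantomStudy-class].
#' @examples
#' ph <- generatePhantom(phantomConfig(), label_lvo = TRUE, seed = 3)
#' hasSign(ph)
#' @export
generatePhantom <- function(config, label_lvo, seed = config$seed, id = "PH") {
  stopifnot(inherits(config, "phantomConfig"))
  n <- config$shape; ns <- config$n_slices
  cand <- 4:9  # candidate lesion slices (1-based), the preprocessing range
  if (ns < max(cand)) stop("n_slices too small to cover the ROI slice range")
  set.seed(seed)
  tpl <- .headTemplate(config)
  vox <- array(0, dim = c(n, n, ns))
  nb <- sum(tpl$brain)
  for (s in seq_len(ns)) {
    sl <- tpl$slice
    sl[tpl$brain] <- sl[tpl$brain] + rnorm(nb, 0, config$noise_sd)
    vox[, , s] <- sl
  }
  centers <- .roiCenters()
  # distractors: calcification/bone mimics, one per candidate slice at rate
  for (s in cand) {
    if (runif(1) < config$distractor_rate) {
      hemi <- sample(c("A", "B"), 1)
      ctr <- centers[[hemi]]
      ang <- runif(1, 0, 2 * pi); rad <- runif(1, 10, 55)
      pos <- c(ctr[["r"]] + rad * cos(ang), ctr[["c"]] + rad * sin(ang))
      vox[, , s] <- .stampDisc(vox[, , s], pos, runif(1, 2, 4), runif(1, 120, 200))
    }
  }
  p_sign <- if (label_lvo) config$p_sign_given_lvo else config$p_sign_given_nolvo
  has_sign <- runif(1) < p_sign
  mask <- array(0L, dim = c(n, n, ns))
  meta <- list()
  if (has_sign) {
    hemi <- sample(c("A", "B"), 1)
    ctr <- centers[[hemi]]
    ang <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1)) * 30
    pos <- c(ctr[["r"]] + rad * cos(ang), ctr[["c"]] + rad * sin(ang))
    lesion_r <- runif(1, 2, 6)
    lesion_i <- runif(1, config$lesion_intensity_range[1],
                      config$lesion_intensity_range[2])
    s <- sample(cand, 1)
    vox[, , s] <- .stampDisc(vox[, , s], pos, lesion_r, lesion_i)
    msl <- matrix(0L, n, n)
    msl <- .stampDisc(msl, pos, lesion_r, 1L)
    mask[, , s] <- msl
    meta <- list(slice = s, center = pos, radius = lesion_r,
                 intensity = lesion_i, hemisphere = hemi)
  }
  if (config$rotation_deg != 0 || any(config$shift_px != 0)) {
    for (s in seq_len(ns)) {
      vox[, , s] <- applyRigid(vox[, , s], config$rotation_deg, config$shift_px)
      mask[, , s] <- applyRigid(mask[, , s], config$rotation_deg, config$shift_px,
                                nearest = TRUE)
    }
    mask <- (mask > 0.5) + 0L
    meta$misaligned <- TRUE
  }
  vol <- new("CTVolume", voxels = vox, pixelMm = config$pixel_mm,
             sliceMm = config$slice_mm, id = id)
  new("PhantomStudy", volume = vol, truthMask = mask,
      hasSign = has_sign, labelLvo = isTRUE(label_lvo), meta = meta)
}

#' Apply an in-plane rigid transform to a slice
#'
#' Rotates by `angle_deg` about the slice centre (positive =
#' counter-clockwise in (row, col) coordinates) and then shifts by
#' `shift_px = c(rows, cols)`, resampling with bilinear interpolation
#' (nearest-neighbour when `nearest = TRUE`, e.g. for binary masks).
#' Out-of-frame source pixels are set to 0.
#'
#' @param slice numeric matrix.
#' @param angle_deg rotation in degrees.
#' @param shift_px length-2 shift in pixels (rows, cols).
#' @param nearest use nearest-neighbour interpolation.
#' @return transformed matrix of the same size.
#' @export
applyRigid <- function(slice, angle_deg, shift_px = c(0, 0), nearest = FALSE) {
  .rigid_warp_cpp(slice, angle_deg, shift_px[1], shift_px[2], nearest)
}

#' Write / read phantom studies as NIfTI
#'
#' `writePhantomNIfTI` writes one volume and one mask file per study
#' (`<id>_vol.nii.gz`, `<id>_mask.nii.gz`) with the configured voxel
#' spacing, plus appends to a `manifest.csv` (id, label, has_sign) when
#' requested. `readCTVolume` reads a volume back into a [CTVolume-class].
#'
#' @param study a [PhantomStudy-class].
#' @param dir output directory.
#' @param id patient identifier used in filenames.
#' @param manifest whether to append to `dir/manifest.csv`.
#' @return invisible character vector of the files written.
#' @export
writePhantomNIfTI <- function(study, dir, id = patientId(study@volume),
                              manifest = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vol <- study@volume
  pd <- c(vol@pixelMm, vol@pixelMm, vol@sliceMm)
  fv <- file.path(dir, paste0(id, "_vol.nii.gz"))
  fm <- file.path(dir, paste0(id, "_mask.nii.gz"))
  iv <- RNifti::asNifti(vol@voxels, pixdim = pd)
  im <- RNifti::asNifti(study@truthMask, pixdim = pd)
  RNifti::writeNifti(iv, fv)
  RNifti::writeNifti(im, fm)
  files <- c(fv, fm)
  if (manifest) {
    mf <- file.path(dir, "manifest.csv")
    row <- data.frame(id = id, label = study@labelLvo, has_sign = study@hasSign)
    write.table(row, mf, sep = ",", row.names = FALSE,
                col.names = !file.exists(mf), append = file.exists(mf))
    files <- c(files, mf)
  }
  invisible(files)
}

#' @rdname writePhantomNIfTI
#' @param path NIfTI file path.
#' @return `readCTVolume` returns a [CTVolume-class].
#' @export
readCTVolume <- function(path, id = sub("_vol\\.nii(\\.gz)?$", "", basename(path))) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  new("CTVolume", voxels = array(as.numeric(img), dim = dim(img)),
      pixelMm = pd[1], sliceMm = pd[3], id = id)
}
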