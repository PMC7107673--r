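# The four-step NCCT preprocessing pipeline: (1) brain extraction,
# (2) in-plane rigid registration to bilateral symmetry, (3) per-slice
# median filtering and intensity windowing to [20, 80], (4) extraction of
# two mirror-image 128 x 128 hemispheric bounding boxes over six candidate
# slices, yielding 12 patches per patient.

#' Extract the brain mask of a head volume
#'
#' Per slice, voxels below the skull threshold are labeled into connected
#' components; components touching the image border (exterior air) are
#' discarded and the largest remaining sub-skull component, after
#' morphological closing, is the brain. Skull-intensity voxels are never
#' included.
#'
#' @param volume a [CTVolume-class].
#' @param config a [preprocessConfig()].
#' @return binary 3-D array of the volume's dimensions.
#' @export
extractBrain <- function(volume, config = preprocessConfig()) {
  vox <- voxels(volume)
  d <- dim(vox)
  if (!any(vox < config$skull_threshold))
    stop("no brain found: no voxel below the skull threshold")
  mask <- array(0L, dim = d)
  brush <- EBImage::makeBrush(2L * config$closing_radius + 1L, "disc")
  lab <- EBImage::bwlabel((vox < config$skull_threshold) + 0)  # frame-wise labels
  found <- FALSE
  for (s in seq_len(d[3])) {
    ls <- lab[, , s]
    border_labels <- unique(c(ls[1, ], ls[d[1], ], ls[, 1], ls[, d[2]]))
    border_labels <- border_labels[border_labels > 0]
    counts <- tabulate(ls)
    if (length(border_labels)) counts[border_labels] <- 0L
    if (!any(counts > 0)) next
    mask[, , s] <- (ls == which.max(counts)) + 0L
    found <- TRUE
  }
  if (!found) stop("no brain found: all slices empty after labeling")
  mask <- EBImage::closing(mask, brush)
  # closing may bleed over skull voxels; never include them
  mask[vox >= config$skull_threshold] <- 0
  (mask > 0.5) + 0L
}

# Mirror a slice across the mid-row axis (the bilateral symmetry axis).
.mirrorRows <- function(x) x[rev(seq_len(nrow(x))), , drop = FALSE]

# Bilateral-symmetry score: correlation between a slice and its mirror.
.symmetryScore <- function(slice) {
  m <- .mirrorRows(slice)
  if (sd(slice) == 0) return(0)
  stats::cor(as.vector(slice), as.vector(m))
}

#' Rigidly register a volume to bilateral symmetry
#'
#' Estimates a single in-plane rigid transform (translation bringing the
#' brain centroid to the image centre, then a rotation chosen by grid
#' search over `config$angle_grid` with local refinement) that maximizes
#' the mirror-correlation symmetry of the middle candidate slice, and
#' applies it to every slice. If the optimized transform does not improve
#' the symmetry score, the identity is used and a warning is emitted.
#'
#' @param volume a [CTVolume-class].
#' @param config a [preprocessConfig()].
#' @param mask optional precomputed brain mask (else [extractBrain()] is
#'   run).
#' @return the registered [CTVolume-class], with attribute `transform`
#'   (list with `angle` in degrees and `shift` in pixels).
#' @export
registerAxial <- function(volume, config = preprocessConfig(), mask = NULL) {
  vox <- voxels(volume)
  d <- dim(vox)
  if (is.null(mask)) mask <- extractBrain(volume, config)
  flat <- rowSums(mask, dims = 2)  # per-(row,col) occupancy over slices
  tot <- sum(flat)
  ctr <- (d[1:2] + 1) / 2
  shift <- c(ctr[1] - sum(rowSums(flat) * seq_len(d[1])) / tot,
             ctr[2] - sum(colSums(flat) * seq_len(d[2])) / tot)
  ref_slice <- config$slice_range[ceiling(length(config$slice_range) / 2)]
  ref <- vox[, , min(ref_slice, d[3])]
  # score candidate angles on a 4x-downsampled slice for speed
  ds <- ref[seq(1, d[1], by = 4), seq(1, d[2], by = 4)]
  score_at <- function(angle)
    .symmetryScore(applyRigid(ds, angle, shift / 4))
  scores <- vapply(config$angle_grid, score_at, numeric(1))
  best <- config$angle_grid[which.max(scores)]
  step <- if (length(config$angle_grid) > 1) diff(config$angle_grid[1:2]) else 0.5
  opt <- stats::optimize(score_at, interval = c(best - step, best + step),
                         maximum = TRUE, tol = 1e-3)
  angle <- opt$maximum
  if (score_at(best) > opt$objective) angle <- best
  before <- .symmetryScore(ref)
  after <- .symmetryScore(applyRigid(ref, angle, shift))
  identity_tf <- FALSE
  if (after < before - 1e-9) {
    # an already-aligned volume legitimately optimizes to ~identity (the
    # tiny interpolation blur loses to the untouched slice); only a failed
    # substantial transform deserves a warning
    if (abs(angle) > 1 || any(abs(shift) > 1))
      warning("registration did not improve symmetry; falling back to identity")
    angle <- 0; shift <- c(0, 0); identity_tf <- TRUE
  }
  out <- vox
  if (!identity_tf && (abs(angle) > 1e-3 || any(abs(shift) > 1e-3))) {
    for (s in seq_len(d[3])) out[, , s] <- applyRigid(vox[, , s], angle, shift)
  } else {
    angle <- if (identity_tf) 0 else angle
  }
  res <- new("CTVolume", voxels = out, pixelMm = volume@pixelMm,
             sliceMm = volume@sliceMm, id = volume@id)
  attr(res, "transform") <- list(angle = angle, shift = shift)
  res
}

# Exact odd-kernel 2-D median with edge replication. 3x3 uses the compiled
# kernel; other sizes fall back to an ordered-statistic reference.
.medianFilter2D <- function(slice, kernel = 3L) {
  if (kernel == 1L) return(slice)
  if (kernel == 3L) return(.median3x3_cpp(slice))
  k <- (kernel - 1L) %/% 2L
  nr <- nrow(slice); nc <- ncol(slice)
  pad <- slice[pmin(pmax(seq(1 - k, nr + k), 1), nr),
               pmin(pmax(seq(1 - k, nc + k), 1), nc)]
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    out[i, j] <- median(pad[i:(i + 2 * k), j:(j + 2 * k)])
  out
}

#' Median filter and intensity windowing
#'
#' Applies a per-slice median filter of size `median_kernel`, then zeroes
#' every voxel outside the `[window_low, window_high]` intensity window
#' (voxels inside are left unchanged). This suppresses bone/calcification
#' (too bright) and CSF/air (too dark) while preserving soft tissue and the
#' hyperdense clot. Windowing is idempotent: applying the window twice
#' equals applying it once.
#'
#' @param volume a [CTVolume-class] or a plain numeric matrix (one slice).
#' @param config a [preprocessConfig()].
#' @return object of the same class as `volume`.
#' @export
setGeneric("denoiseWindow",
           function(volume, config = preprocessConfig()) standardGeneric("denoiseWindow"))

#' @rdname denoiseWindow
#' @export
setMethod("denoiseWindow", "CTVolume", function(volume, config) {
  vox <- voxels(volume)
  for (s in seq_len(dim(vox)[3])) {
    sl <- .medianFilter2D(vox[, , s], config$median_kernel)
    sl[sl < config$window_low | sl > config$window_high] <- 0
    vox[, , s] <- sl
  }
  new("CTVolume", voxels = vox, pixelMm = volume@pixelMm,
      sliceMm = volume@sliceMm, id = volume@id)
})

#' @rdname denoiseWindow
#' @export
setMethod("denoiseWindow", "matrix", function(volume, config) {
  sl <- .medianFilter2D(volume, config$median_kernel)
  sl[sl < config$window_low | sl > config$window_high] <- 0
  sl
})

# 1-based row/col index ranges of a 0-based half-open box.
.boxIdx <- function(box) list(rows = (box$rows[1] + 1L):box$rows[2],
                              cols = (box$cols[1] + 1L):box$cols[2])

#' Crop the hemispheric ROI patches
#'
#' Extracts the two mirror-image 128 x 128 bounding boxes (hemisphere A
#' then B) from each slice in `config$slice_range`, in slice-major order,
#' giving the patient's 12 candidate patches.
#'
#' @param volume a registered, windowed [CTVolume-class].
#' @param config a [preprocessConfig()].
#' @return an [ROIStack-class].
#' @export
cropROI <- function(volume, config = preprocessConfig()) {
  vox <- voxels(volume)
  if (dim(vox)[3] < max(config$slice_range))
    stop("insufficient slices for the configured slice range")
  a <- .boxIdx(config$box_a); b <- .boxIdx(config$box_b)
  patches <- vector("list", 2L * length(config$slice_range))
  prov <- data.frame(slice = rep(config$slice_range, each = 2),
                     hemisphere = rep(c("A", "B"), length(config$slice_range)),
                     stringsAsFactors = FALSE)
  k <- 1L
  for (s in config$slice_range) {
    patches[[k]] <- vox[a$rows, a$cols, s]; k <- k + 1L
    patches[[k]] <- vox[b$rows, b$cols, s]; k <- k + 1L
  }
  names(patches) <- sprintf("%s_s%02d_%s", volume@id, prov$slice, prov$hemisphere)
  new("ROIStack", patientId = volume@id, patches = patches, provenance = prov)
}

#' Run the full preprocessing pipeline on one volume
#'
#' Brain extraction (masking out skull and exterior), rigid registration,
#' median filtering + windowing, and ROI cropping, in that order.
#'
#' @param volume a [CTVolume-class].
#' @param config a [preprocessConfig()].
#' @return an [ROIStack-class]; the applied rigid transform is attached as
#'   attribute `transform`.
#' @export
preprocessVolume <- function(volume, config = preprocessConfig()) {
  mask <- extractBrain(volume, config)
  vox <- voxels(volume) * mask
  masked <- new("CTVolume", voxels = vox, pixelMm = volume@pixelMm,
                sliceMm = volume@sliceMm, id = volume@id)
  reg <- registerAxial(masked, config, mask = mask)
  tf <- attr(reg, "transform")
  den <- denoiseWindow(reg, config)
  stack <- cropROI(den, config)
  attr(stack, "transform") <- tf
  stack
}

#' Preprocess a phantom study, carrying its truth mask along
#'
#' Applies [preprocessVolume()] to the phantom volume and transforms the
#' ground-truth lesion mask with the same rigid transform
#' (nearest-neighbour) and the same crop, so segmentation training data
#' stay geometrically aligned with the patches.
#'
#' @param study a [PhantomStudy-class].
#' @param config a [preprocessConfig()].
#' @return list with elements `stack` (the [ROIStack-class]) and `masks`
#'   (list of 12 binary 128 x 128 matrices, same order as the patches).
#' @export
preprocessStudy <- function(study, config = preprocessConfig()) {
  stack <- preprocessVolume(study@volume, config)
  tf <- attr(stack, "transform")
  msk <- truthMask(study)
  a <- .boxIdx(config$box_a); b <- .boxIdx(config$box_b)
  masks <- vector("list", 12L)
  k <- 1L
  for (s in config$slice_range) {
    msl <- msk[, , s]
    if (abs(tf$angle) > 1e-3 || any(abs(tf$shift) > 1e-3))
      msl <- (applyRigid(msl, tf$angle, tf$shift, nearest = TRUE) > 0.5) + 0L
    masks[[k]] <- msl[a$rows, a$cols]; k <- k + 1L
    masks[[k]] <- msl[b$rows, b$cols]; k <- k + 1L
  }
  names(masks) <- names(patches(stack))
  list(stack = stack, masks = masks)
}
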