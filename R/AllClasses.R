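#' CTVolume: an axial non-contrast head CT volume
#'
#' Voxels are stored as a 3-D array indexed `[row, col, slice]` with a
#' 512 x 512 in-plane matrix per axial slice, mirroring the fixed
#' field-of-view of the thick-cut stroke protocol the pipeline assumes
#' (0.426 mm in-plane pixels, 5 mm slices, at least 10 slices).
#'
#' @slot voxels 3-D numeric array, 512 x 512 x S with S >= 10.
#' @slot pixelMm in-plane pixel spacing in millimetres.
#' @slot sliceMm slice thickness in millimetres.
#' @slot id patient identifier.
#' @export
setClass("CTVolume",
  representation(voxels = "array", pixelMm = "numeric", sliceMm = "numeric",
                 id = "character"),
  prototype(pixelMm = 0.426, sliceMm = 5.0, id = "ct"))

setValidity("CTVolume", function(object) {
  d <- dim(object@voxels)
  if (length(d) != 3L) return("voxels must be a 3-D array [row, col, slice]")
  if (d[1] != 512L || d[2] != 512L) return("in-plane shape must be exactly 512 x 512")
  if (d[3] < 10L) return("volume must have at least 10 slices")
  if (length(object@id) != 1L) return("id must be a single string")
  TRUE
})

#' ROIStack: the 12 cropped candidate patches of one patient
#'
#' Preprocessing reduces a head volume to 12 patches of 128 x 128: two
#' mirror-image hemispheric bounding boxes over each of six candidate
#' slices, ordered slice-major / hemisphere-minor.
#'
#' @slot patientId patient identifier.
#' @slot patches list of 12 numeric 128 x 128 matrices.
#' @slot provenance data.frame with one row per patch: `slice` (1-based
#'   slice index in the source volume) and `hemisphere` ("A" or "B").
#' @export
setClass("ROIStack",
  representation(patientId = "character", patches = "list",
                 provenance = "data.frame"))

setValidity("ROIStack", function(object) {
  if (length(object@patches) != 12L) return("an ROIStack holds exactly 12 patches")
  ok <- vapply(object@patches, function(p) is.matrix(p) && all(dim(p) == c(128L, 128L)),
               logical(1))
  if (!all(ok)) return("every patch must be a 128 x 128 matrix")
  if (nrow(object@provenance) != 12L) return("provenance must have 12 rows")
  if (!all(c("slice", "hemisphere") %in% names(object@provenance)))
    return("provenance needs columns slice, hemisphere")
  TRUE
})

#' PhantomStudy: one synthetic patient's pseudo-CT study
#'
#' @slot volume a [CTVolume-class].
#' @slot truthMask binary 3-D array marking MCA-sign lesion voxels (all zero
#'   when the sign is absent).
#' @slot hasSign whether the hyperdense MCA sign was planted.
#' @slot labelLvo the LVO diagnosis label driving the sign probability.
#' @slot meta list of generator internals (lesion slice, centre, radius,
#'   hemisphere, intensity) used by geometric audits.
#' @export
setClass("PhantomStudy",
  representation(volume = "CTVolume", truthMask = "array", hasSign = "logical",
                 labelLvo = "logical", meta = "list"))

setValidity("PhantomStudy", function(object) {
  if (!identical(dim(object@truthMask), dim(object@volume@voxels)))
    return("truthMask must match the volume dimensions")
  nz <- sum(object@truthMask) > 0
  if (nz != object@hasSign) return("truthMask must be nonempty iff hasSign")
  TRUE
})

#' SegNet: encoder-decoder fully convolutional segmentation network
#'
#' A U-Net-style network mapping a square intensity patch to a per-pixel
#' lesion probability map, with a global-max-pool feature head over the
#' bottleneck maps. Weights live in `params`; `state` carries optimizer
#' moments during training.
#'
#' @slot config network configuration, see [segNetConfig()].
#' @slot params list of convolution weights/biases.
#' @slot state optimizer state (Adam moments) and training history.
#' @slot trained whether [trainSegmenter()] has been run.
#' @slot fingerprint short hash of config + training settings.
#' @export
setClass("SegNet",
  representation(config = "list", params = "list", state = "list",
                 trained = "logical", fingerprint = "character"),
  prototype(trained = FALSE, fingerprint = ""))

#' DeepFeatures: one patient's global-max-pool feature vector
#'
#' @slot patientId patient identifier.
#' @slot values numeric vector, one value per bottleneck channel; each entry
#'   is the maximum activation of that channel over the representative
#'   slice's two hemispheric patches.
#' @slot sourceSlice index (1..6 within the candidate range) of the slice
#'   chosen to represent the patient.
#' @export
setClass("DeepFeatures",
  representation(patientId = "character", values = "numeric",
                 sourceSlice = "integer"))

#' TrainedLevelModel: a fitted learner bound to its deployment state
#'
#' @slot family one of `"lr"`, `"rf"`, `"svm"`, `"xgb"`.
#' @slot level feature level 1, 2 or 3.
#' @slot fit the underlying fitted object.
#' @slot featureList ordered model column names.
#' @slot imputer KNN imputation state fitted on training data (NULL for
#'   gradient boosting, which consumes raw missing values).
#' @slot cutoff probability threshold chosen by cross-validated Youden index.
#' @slot importance per-feature scores (tree families), else NULL.
#' @slot extras family-specific state (factor level templates, calibration,
#'   fallback flags).
#' @export
setClass("TrainedLevelModel",
  representation(family = "character", level = "integer", fit = "ANY",
                 featureList = "character", imputer = "ANY", cutoff = "numeric",
                 importance = "ANY", extras = "list"),
  prototype(cutoff = 0.5, extras = list()))

setValidity("TrainedLevelModel", function(object) {
  if (!object@family %in% c("lr", "rf", "svm", "xgb"))
    return("family must be one of lr, rf, svm, xgb")
  if (!(object@cutoff > 0 && object@cutoff < 1) && !is.na(object@cutoff))
    return("cutoff must lie in (0,1)")
  if (object@family == "xgb" && !is.null(object@imputer))
    return("gradient boosting carries no imputation state")
  TRUE
})

#' MetricsReport: classification metrics for a labeled prediction set
#'
#' All quantities are recomputed from the stored confusion counts and must
#' satisfy the defining identities, in particular the Youden index
#' gamma = sensitivity + specificity - 1.
#'
#' @slot youden Youden index gamma.
#' @slot accuracy fraction correct.
#' @slot recall sensitivity TP / (TP + FN).
#' @slot specificity TN / (TN + FP).
#' @slot f1 F1 score 2TP / (2TP + FP + FN).
#' @slot auc trapezoidal area under the ROC curve.
#' @slot cutoff the probability threshold used (score >= cutoff is positive).
#' @slot confusion named integer vector TP, FP, TN, FN.
#' @export
setClass("MetricsReport",
  representation(youden = "numeric", accuracy = "numeric", recall = "numeric",
                 specificity = "numeric", f1 = "numeric", auc = "numeric",
                 cutoff = "numeric", confusion = "integer"))

setValidity("MetricsReport", function(object) {
  cm <- object@confusion
  if (!all(c("TP", "FP", "TN", "FN") %in% names(cm)))
    return("confusion must be named TP, FP, TN, FN")
  tp <- cm[["TP"]]; fp <- cm[["FP"]]; tn <- cm[["TN"]]; fn <- cm[["FN"]]
  tol <- 1e-9
  if (abs(object@youden - (object@recall + object@specificity - 1)) > tol)
    return("youden must equal recall + specificity - 1")
  if (abs(object@accuracy - (tp + tn) / (tp + fp + tn + fn)) > tol)
    return("accuracy must equal (TP+TN)/total")
  fr <- c(object@accuracy, object@recall, object@specificity, object@f1, object@auc)
  if (any(fr < -tol | fr > 1 + tol)) return("fractions must lie in [0,1]")
  if (object@youden < -1 - tol || object@youden > 1 + tol)
    return("youden must lie in [-1,1]")
  TRUE
})
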