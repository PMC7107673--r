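#' Accessors for strokehier objects
#'
#' Small accessor generics so that downstream code never touches slots.
#'
#' @param object a strokehier S4 object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setMethod("voxels", "CTVolume", function(object) object@voxels)
#' @rdname accessors
#' @export
setMethod("voxels", "PhantomStudy", function(object) object@volume@voxels)

#' @rdname accessors
#' @export
setGeneric("patientId", function(object) standardGeneric("patientId"))
#' @rdname accessors
#' @export
setMethod("patientId", "CTVolume", function(object) object@id)
#' @rdname accessors
#' @export
setMethod("patientId", "ROIStack", function(object) object@patientId)
#' @rdname accessors
#' @export
setMethod("patientId", "DeepFeatures", function(object) object@patientId)

#' @rdname accessors
#' @export
setGeneric("patches", function(object) standardGeneric("patches"))
#' @rdname accessors
#' @export
setMethod("patches", "ROIStack", function(object) object@patches)

#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setMethod("provenance", "ROIStack", function(object) object@provenance)

#' @rdname accessors
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setMethod("featureValues", "DeepFeatures", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("sourceSlice", function(object) standardGeneric("sourceSlice"))
#' @rdname accessors
#' @export
setMethod("sourceSlice", "DeepFeatures", function(object) object@sourceSlice)

#' @rdname accessors
#' @export
setGeneric("truthMask", function(object) standardGeneric("truthMask"))
#' @rdname accessors
#' @export
setMethod("truthMask", "PhantomStudy", function(object) object@truthMask)

#' @rdname accessors
#' @export
setGeneric("hasSign", function(object) standardGeneric("hasSign"))
#' @rdname accessors
#' @export
setMethod("hasSign", "PhantomStudy", function(object) object@hasSign)

#' @rdname accessors
#' @export
setGeneric("lvoLabel", function(object) standardGeneric("lvoLabel"))
#' @rdname accessors
#' @export
setMethod("lvoLabel", "PhantomStudy", function(object) object@labelLvo)

#' @rdname accessors
#' @export
setGeneric("modelCutoff", function(object) standardGeneric("modelCutoff"))
#' @rdname accessors
#' @export
setMethod("modelCutoff", "TrainedLevelModel", function(object) object@cutoff)
#' @rdname accessors
#' @export
setMethod("modelCutoff", "MetricsReport", function(object) object@cutoff)

#' @rdname accessors
#' @export
setGeneric("confusionCounts", function(object) standardGeneric("confusionCounts"))
#' @rdname accessors
#' @export
setMethod("confusionCounts", "MetricsReport", function(object) object@confusion)

#' @rdname accessors
#' @export
setGeneric("isTrained", function(object) standardGeneric("isTrained"))
#' @rdname accessors
#' @export
setMethod("isTrained", "SegNet", function(object) object@trained)

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat("CTVolume", object@id, ":", d[1], "x", d[2], "x", d[3],
      sprintf("(%.3f mm px, %.1f mm slices)\n", object@pixelMm, object@sliceMm))
})

setMethod("show", "ROIStack", function(object) {
  cat("ROIStack for", object@patientId, ":", length(object@patches),
      "patches over slices", paste(unique(object@provenance$slice), collapse = ","), "\n")
})

setMethod("show", "PhantomStudy", function(object) {
  cat("PhantomStudy:", ifelse(object@labelLvo, "LVO", "no LVO"), "|",
      ifelse(object@hasSign, "MCA sign present", "no MCA sign"), "|",
      sum(object@truthMask), "lesion voxels\n")
})

setMethod("show", "SegNet", function(object) {
  cfg <- object@config
  cat(sprintf("SegNet: input %dx%d, depth %d, base %d, bottleneck %d [%s]\n",
              cfg$input_size, cfg$input_size, cfg$depth, cfg$base_channels,
              cfg$bottleneck_channels,
              ifelse(object@trained, "trained", "untrained")))
})

setMethod("show", "DeepFeatures", function(object) {
  cat("DeepFeatures for", object@patientId, ":", length(object@values),
      "channels from candidate slice", object@sourceSlice, "\n")
})

setMethod("show", "TrainedLevelModel", function(object) {
  cat(sprintf("TrainedLevelModel: family %s, level %d, %d features, cutoff %.3f\n",
              object@family, object@level, length(object@featureList), object@cutoff))
})

setMethod("show", "MetricsReport", function(object) {
  cm <- object@confusion
  cat(sprintf(
    "MetricsReport: youden %.3f | acc %.3f | recall %.3f | spec %.3f | F1 %.3f | AUC %.3f\n",
    object@youden, object@accuracy, object@recall, object@specificity,
    object@f1, object@auc))
  cat(sprintf("  cutoff %.4f, confusion TP=%d FP=%d TN=%d FN=%d\n",
              object@cutoff, cm[["TP"]], cm[["FP"]], cm[["TN"]], cm[["FN"]]))
})
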