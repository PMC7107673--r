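# Level-3 feature construction: two-sample t screening of the deep feature
# channels and assembly of the three nested model tables.

#' Two-sample t-test screening of deep feature channels
#'
#' Splits patients by LVO label and computes a per-channel two-sample
#' t-test (pooled-variance Student by default, Welch behind a flag),
#' returning the `top_k` channels with the smallest p-values. Constant
#' channels receive p = 1; ties in p break by channel index. Screening is
#' meant to run on training patients only, with the selected indices frozen
#' and applied unchanged to test patients.
#'
#' @param features numeric matrix, one row per patient, one column per
#'   channel.
#' @param labels logical (or 0/1) LVO labels.
#' @param top_k number of channels to keep.
#' @param welch use the Welch (unequal-variance) statistic.
#' @return list with `indices` (selected channel indices, ascending p),
#'   `p` (all channel p-values) and `order` (full ranking).
#' @export
ttestScreen <- function(features, labels, top_k = 10L, welch = FALSE) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present for screening")
  if (sum(labels) < 2L || sum(!labels) < 2L)
    stop("need at least 2 patients per class")
  x1 <- features[labels, , drop = FALSE]
  x0 <- features[!labels, , drop = FALSE]
  n1 <- nrow(x1); n0 <- nrow(x0)
  m1 <- colMeans(x1); m0 <- colMeans(x0)
  v1 <- apply(x1, 2L, stats::var); v0 <- apply(x0, 2L, stats::var)
  if (welch) {
    se2 <- v1 / n1 + v0 / n0
    tt <- (m1 - m0) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    tt <- (m1 - m0) / sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2, length(tt))
  }
  p <- 2 * pt(-abs(tt), df)
  p[!is.finite(tt) & abs(m1 - m0) > 0] <- 0   # separated, zero within-class var
  p[is.na(p)] <- 1                            # constant channels
  ord <- order(p, seq_along(p))
  list(indices = ord[seq_len(min(top_k, length(p)))], p = p, order = ord)
}

#' Assemble the model-ready table for one feature level
#'
#' Level-1 holds demographics and bystander-observable deficits; Level-2
#' adds clinical history, vital signs and GCS; Level-3 appends the selected
#' deep imaging feature columns (named `f0001`, `f0002`, ... by channel).
#' Column order is deterministic; patient ids become row names, and the
#' label column is dropped.
#'
#' @param level 1, 2 or 3.
#' @param cohort cohort data.frame from [generateCohort()].
#' @param deep_features numeric matrix of deep features with rownames equal
#'   to patient ids (required for level 3).
#' @param selected channel indices chosen by [ttestScreen()] (required for
#'   level 3).
#' @return a data.frame of predictors, rownames = patient ids.
#' @export
assembleLevel <- function(level, cohort, deep_features = NULL, selected = NULL) {
  level <- as.integer(level)
  stopifnot(level %in% 1:3)
  cols <- levelColumns(cohort, if (level == 1L) "1" else "2")
  tab <- cohort[, cols, drop = FALSE]
  rownames(tab) <- cohort$id
  if (level == 3L) {
    if (is.null(deep_features) || is.null(selected))
      stop("Level-3 requires deep features and selected channel indices")
    df <- deep_features[match(cohort$id, rownames(deep_features)), selected,
                        drop = FALSE]
    if (anyNA(df[, 1L]) && nrow(cohort) > 0)
      stop("deep features missing for some cohort patients")
    colnames(df) <- sprintf("f%04d", selected)
    tab <- cbind(tab, as.data.frame(df))
    rownames(tab) <- cohort$id
  }
  tab
}

#' Bind per-patient deep feature vectors into a matrix
#'
#' @param feature_list list of [DeepFeatures-class] objects.
#' @return numeric matrix with patient ids as rownames.
#' @export
deepFeatureMatrix <- function(feature_list) {
  m <- do.call(rbind, lapply(feature_list, featureValues))
  rownames(m) <- vapply(feature_list, patientId, character(1))
  colnames(m) <- sprintf("f%04d", seq_len(ncol(m)))
  m
}
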