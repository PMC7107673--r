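# Performance evaluation: Youden-index cutoff selection via stratified
# 10-fold cross-validation, the confusion-matrix metric suite, trapezoidal
# AUC, and the univariate cohort-summary statistics engine.

#' Youden index
#'
#' `gamma = sensitivity + specificity - 1`, the balanced-accuracy criterion
#' used to pick probability cutoffs.
#'
#' @param sensitivity,specificity fractions in \[0,1\].
#' @return gamma in \[-1,1\].
#' @export
youden <- function(sensitivity, specificity) {
  stopifnot(all(sensitivity >= 0 & sensitivity <= 1),
            all(specificity >= 0 & specificity <= 1))
  sensitivity + specificity - 1
}

#' Best Youden cutoff over observed scores
#'
#' Scans the unique observed scores as cutoff candidates (prediction
#' positive iff score >= cutoff) and returns the candidate maximizing the
#' empirical Youden index; ties break to the smallest candidate.
#'
#' @param labels binary labels.
#' @param scores numeric scores in \[0,1\].
#' @return list with `cutoff` and the achieved `gamma`.
#' @export
bestCutoff <- function(labels, scores) {
  labels <- as.logical(labels)
  cand <- sort(unique(scores))
  np <- sum(labels); nn <- sum(!labels)
  g <- vapply(cand, function(ct) {
    pred <- scores >= ct
    sum(pred & labels) / np + sum(!pred & !labels) / nn - 1
  }, numeric(1))
  best <- max(g)
  list(cutoff = cand[which(g >= best - 1e-12)][1], gamma = best)
}

#' Select a probability cutoff by stratified 10-fold cross-validation
#'
#' Splits the training data into `n_folds` label-stratified folds, refits
#' the full model policy (imputation, selection, fitting) on each
#' training complement, pools the out-of-fold scores, and picks the pooled
#' score maximizing the empirical Youden index (smallest candidate on
#' ties). Deterministic given `config$seed`.
#'
#' @param family model family passed to [trainLevelModel()].
#' @param table raw predictor data.frame.
#' @param labels logical outcome.
#' @param config a [cutoffConfig()].
#' @param level level recorded on fold models.
#' @return list with `cutoff`, `gamma`, and the pooled out-of-fold
#'   `scores`.
#' @export
selectCutoffCV <- function(family, table, labels, config = cutoffConfig(),
                           level = 1L) {
  labels <- as.logical(labels)
  n <- length(labels)
  if (sum(labels) < config$n_folds || sum(!labels) < config$n_folds)
    stop("need at least n_folds patients of each class for stratification")
  set.seed(config$seed)
  fold <- integer(n)
  for (cl in c(TRUE, FALSE)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(config$n_folds), length(idx))
  }
  scores <- numeric(n)
  for (f in seq_len(config$n_folds)) {
    tr <- fold != f
    if (length(unique(labels[tr])) < 2L) stop("a class is absent from a fold")
    m <- trainLevelModel(family, table[tr, , drop = FALSE], labels[tr],
                         level = level, seed = config$seed + f)
    scores[!tr] <- predictModel(m, table[!tr, , drop = FALSE])
  }
  bc <- bestCutoff(labels, scores)
  list(cutoff = bc$cutoff, gamma = bc$gamma, scores = scores, fold = fold)
}

#' Trapezoidal ROC AUC
#'
#' Area under the receiver operating characteristic curve, equal to the
#' probability that a random positive outscores a random negative (ties
#' counted 1/2).
#'
#' @param labels binary labels.
#' @param scores numeric scores.
#' @return AUC in \[0,1\].
#' @export
rocAUC <- function(labels, scores) {
  labels <- as.logical(labels)
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                 levels = c(FALSE, TRUE), direction = "<",
                                 quiet = TRUE)))
}

#' Confusion-matrix metric report
#'
#' Predictions are positive iff `score >= cutoff`. Returns the full metric
#' suite; the stored Youden index always satisfies
#' `gamma = recall + specificity - 1` exactly (enforced by the class
#' validity).
#'
#' @param labels binary labels.
#' @param scores numeric scores in \[0,1\].
#' @param cutoff probability threshold.
#' @return a [MetricsReport-class].
#' @export
confusionMetrics <- function(labels, scores, cutoff = 0.5) {
  labels <- as.logical(labels)
  if (!length(labels)) stop("empty input")
  pred <- scores >= cutoff
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  tn <- sum(!pred & !labels); fn <- sum(!pred & labels)
  recall <- if (tp + fn > 0) tp / (tp + fn) else NaN
  specificity <- if (tn + fp > 0) tn / (tn + fp) else NaN
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  auc <- if (length(unique(labels)) == 2L) rocAUC(labels, scores) else NaN
  new("MetricsReport",
      youden = recall + specificity - 1,
      accuracy = (tp + tn) / length(labels),
      recall = recall, specificity = specificity, f1 = f1, auc = auc,
      cutoff = cutoff,
      confusion = c(TP = as.integer(tp), FP = as.integer(fp),
                    TN = as.integer(tn), FN = as.integer(fn)))
}

#' Exact chi-square tail probability at 2 degrees of freedom
#'
#' For df = 2 the chi-square survival function has the closed form
#' `p = exp(-x/2)`; used by [tableOne()] for 2 x 3 tables with an Unknown
#' level.
#'
#' @param statistic chi-square statistic.
#' @return upper-tail p-value.
#' @export
chi2df2P <- function(statistic) exp(-statistic / 2)

#' Univariate cohort summary tests
#'
#' For each predictor column of a labeled cohort: continuous variables get
#' a pooled-variance two-sample Student t-test; categorical variables are
#' tabulated against the LVO label with missingness as an explicit
#' "Unknown" level, then routed to Fisher's exact test when any expected
#' cell count is below 5, a Yates continuity-corrected Pearson chi-square
#' for 2 x 2 tables, and an uncorrected Pearson chi-square otherwise (with
#' the df = 2 closed form for 2 x 3 tables).
#'
#' @param cohort labeled cohort data.frame (column `lvo` plus predictors).
#' @param fisher_all also report Fisher's exact p for every 2 x 2 table
#'   (column `p_fisher`), regardless of routing.
#' @return data.frame with variable, test, statistic and p columns.
#' @export
tableOne <- function(cohort, fisher_all = FALSE) {
  labels <- as.logical(cohort$lvo)
  if (length(unique(labels)) < 2L) stop("cohort must contain both classes")
  vars <- setdiff(names(cohort), c("id", "lvo"))
  rows <- lapply(vars, function(nm) {
    col <- cohort[[nm]]
    if (is.numeric(col)) {
      ok <- !is.na(col)
      tt <- stats::t.test(col[ok & labels], col[ok & !labels], var.equal = TRUE)
      data.frame(variable = nm, test = "student-t",
                 statistic = unname(tt$statistic), p = tt$p.value,
                 p_fisher = NA_real_, stringsAsFactors = FALSE)
    } else {
      col <- as.character(col)
      col[is.na(col)] <- "Unknown"
      tab <- table(factor(labels, levels = c(TRUE, FALSE)), col)
      res <- .categoricalTest(tab)
      pf <- if (fisher_all && ncol(tab) == 2L)
        fisher.test(tab)$p.value else NA_real_
      data.frame(variable = nm, test = res$test, statistic = res$statistic,
                 p = res$p, p_fisher = pf, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (!fisher_all) out$p_fisher <- NULL
  rownames(out) <- NULL
  out
}

# Routing for one class-by-level contingency table.
.categoricalTest <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ft <- fisher.test(tab)
    return(list(test = "fisher-exact", statistic = NA_real_, p = ft$p.value))
  }
  if (ncol(tab) == 2L) {
    ct <- suppressWarnings(chisq.test(tab, correct = TRUE))
    return(list(test = "chi-square-yates-2x2",
                statistic = unname(ct$statistic), p = ct$p.value))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  df <- unname(ct$parameter)
  p <- if (df == 2L) chi2df2P(unname(ct$statistic)) else ct$p.value
  list(test = if (df == 2L) "chi-square-df2-with-unknown" else "chi-square",
       statistic = unname(ct$statistic), p = p)
}
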