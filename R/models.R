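# The four tabular learner families and the missing-data policies.
#
# Policy summary: categorical missingness becomes an explicit "Unknown"
# level; continuous missingness is KNN-median imputed for logistic
# regression, random forest and SVM; gradient boosting consumes the raw
# table and learns default split directions for missing entries. The SVM
# has no intrinsic variable selection and is fitted on the features the
# gradient-boosting model found useful (positive total gain).

#' Encode categorical missingness as an explicit "Unknown" level
#'
#' Every missing cell of a character or factor column becomes the literal
#' level `"Unknown"`; observed cells and continuous columns are untouched.
#'
#' @param table a data.frame of predictors.
#' @return the encoded data.frame (categorical columns as character).
#' @export
encodeUnknown <- function(table) {
  for (nm in names(table)) {
    col <- table[[nm]]
    if (is.factor(col)) col <- as.character(col)
    if (is.character(col)) {
      col[is.na(col)] <- "Unknown"
      table[[nm]] <- col
    }
  }
  table
}

#' Fit the KNN-median imputation state on training data
#'
#' Stores training means/SDs (for standardization), training medians (the
#' last-resort fallback) and the standardized training matrix. Distances
#' between a query and a training row are Euclidean over their jointly
#' observed standardized continuous features (scaled by the number of
#' shared features so rows with different missingness patterns are
#' comparable).
#'
#' @param table training data.frame (continuous columns may contain NA).
#' @param k neighbors used at imputation time.
#' @return an `imputeState` list, usable on any future row via
#'   [imputeTable()].
#' @export
fitImputer <- function(table, k = 5L) {
  cont <- names(table)[vapply(table, is.numeric, logical(1))]
  X <- as.matrix(table[, cont, drop = FALSE])
  mu <- colMeans(X, na.rm = TRUE)
  sdv <- apply(X, 2L, sd, na.rm = TRUE)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  mu[!is.finite(mu)] <- 0
  med <- apply(X, 2L, median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  Z <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  structure(list(cont = cont, mean = mu, sd = sdv, median = med,
                 Z = Z, values = X, k = as.integer(k)),
            class = "imputeState")
}

#' Impute missing continuous cells with KNN medians
#'
#' Each missing continuous cell of each row is replaced by the median of
#' that column among the `k` training neighbors nearest to the row (ties in
#' distance break by training-row order; neighbors must have the target
#' column observed). Rows sharing no observed feature with the training
#' basis fall back to the training-column median. Only training state is
#' used, so the result for a row never depends on the other query rows.
#'
#' @param state an `imputeState` from [fitImputer()].
#' @param table data.frame to complete (same continuous columns).
#' @return the completed data.frame.
#' @export
imputeTable <- function(state, table) {
  stopifnot(inherits(state, "imputeState"))
  cont <- state$cont
  for (r in seq_len(nrow(table))) {
    row <- as.numeric(table[r, cont])
    miss <- which(is.na(row))
    if (!length(miss)) next
    zq <- (row - state$mean) / state$sd
    obs <- which(!is.na(zq))
    for (m in miss) {
      cand <- which(!is.na(state$values[, m]))
      if (!length(obs) || !length(cand)) {
        table[r, cont[m]] <- state$median[m]
        next
      }
      D <- state$Z[cand, obs, drop = FALSE]
      df2 <- sweep(D, 2L, zq[obs])^2
      shared <- rowSums(!is.na(df2))
      dist <- sqrt(rowSums(df2, na.rm = TRUE) / pmax(shared, 1L))
      dist[shared == 0L] <- Inf
      if (all(!is.finite(dist))) {
        table[r, cont[m]] <- state$median[m]
        next
      }
      ord <- cand[order(dist, cand)]
      nb <- ord[seq_len(min(state$k, length(ord)))]
      table[r, cont[m]] <- median(state$values[nb, m])
    }
  }
  table
}

# Factor level templates frozen at training time; unseen levels at predict
# time map to "Unknown" when available, else to the first training level.
.factorTemplate <- function(table) {
  lv <- lapply(table, function(col)
    if (is.character(col) || is.factor(col)) sort(unique(as.character(col))) else NULL)
  lv[!vapply(lv, is.null, logical(1))]
}

.applyFactorTemplate <- function(table, template) {
  for (nm in names(template)) {
    col <- as.character(table[[nm]])
    bad <- !(col %in% template[[nm]]) & !is.na(col)
    if (any(bad))
      col[bad] <- if ("Unknown" %in% template[[nm]]) "Unknown" else template[[nm]][1]
    table[[nm]] <- factor(col, levels = template[[nm]])
  }
  table
}

# One-hot design matrix; continuous columns pass through (NA preserved,
# which is what gradient boosting consumes). Factors must be NA-free.
.designMatrix <- function(table, template) {
  table <- .applyFactorTemplate(table, template)
  blocks <- lapply(names(table), function(nm) {
    col <- table[[nm]]
    if (is.factor(col)) {
      m <- sapply(levels(col), function(l) as.numeric(col == l))
      m <- matrix(m, nrow = nrow(table),
                  dimnames = list(NULL, paste0(nm, "=", levels(col))))
      m
    } else {
      matrix(as.numeric(col), ncol = 1, dimnames = list(NULL, nm))
    }
  })
  do.call(cbind, blocks)
}

# Suppress the routine glm separation/convergence warnings but remember them.
.quietGlm <- function(formula, data) {
  flag <- FALSE
  fit <- withCallingHandlers(
    glm(formula, data = data, family = binomial()),
    warning = function(w) {
      flag <<- TRUE
      invokeRestart("muffleWarning")
    })
  attr(fit, "glm_warned") <- flag
  fit
}

.waldP <- function(fit, terms) {
  an <- try(suppressWarnings(car::Anova(fit, type = "II", test.statistic = "Wald")),
            silent = TRUE)
  if (inherits(an, "try-error")) return(setNames(rep(NA_real_, length(terms)), terms))
  p <- an[, "Pr(>Chisq)"]
  names(p) <- rownames(an)
  p[terms]
}

#' Bidirectional stepwise logistic regression
#'
#' Starts from the empty model and alternates forward and backward sweeps:
#' the most significant excluded term enters while its Wald p < `p_enter`,
#' the least significant included term leaves while its Wald p >
#' `p_remove`. A term removed in a sweep may not immediately re-enter in
#' the same sweep, which prevents cycling. Perfect separation triggers a
#' ridge-penalized refit of the selected terms (with a warning).
#'
#' @param table imputed, Unknown-encoded data.frame of predictors.
#' @param labels logical outcome.
#' @param p_enter,p_remove entry/removal Wald p thresholds.
#' @return list with the fitted `glm` (or penalized fallback), `selected`
#'   term names, `template` factor levels, and `penalized` flag.
#' @export
fitStepwiseLogistic <- function(table, labels, p_enter = 0.05, p_remove = 0.10) {
  template <- .factorTemplate(table)
  tab <- .applyFactorTemplate(table, template)
  # drop constant columns (nothing to estimate)
  keep <- vapply(tab, function(c) length(unique(c[!is.na(c)])) > 1L, logical(1))
  tab <- tab[, keep, drop = FALSE]
  d <- cbind(.y = as.numeric(labels), tab)
  candidates <- names(tab)
  selected <- character(0)
  warned <- FALSE
  history <- character(0)
  for (sweep_i in 1:50) {
    changed <- FALSE
    just_removed <- character(0)
    # backward: drop the worst included term first
    if (length(selected)) {
      f <- .quietGlm(as.formula(paste(".y ~", paste(selected, collapse = "+"))), d)
      warned <- warned || attr(f, "glm_warned")
      p <- .waldP(f, selected)
      p[is.na(p)] <- 0
      if (max(p) > p_remove) {
        worst <- selected[which.max(p)]
        selected <- setdiff(selected, worst)
        just_removed <- worst
        changed <- TRUE
      }
    }
    # forward: add the best excluded term
    pool <- setdiff(candidates, c(selected, just_removed))
    if (length(pool)) {
      pv <- vapply(pool, function(cand) {
        f <- .quietGlm(as.formula(paste(".y ~", paste(c(selected, cand), collapse = "+"))), d)
        p <- .waldP(f, cand)
        if (is.na(p)) 1 else p
      }, numeric(1))
      if (min(pv) < p_enter) {
        selected <- c(selected, pool[which.min(pv)])
        changed <- TRUE
      }
    }
    key <- paste(sort(selected), collapse = "|")
    if (key %in% history) break
    history <- c(history, key)
    if (!changed) break
  }
  rhs <- if (length(selected)) paste(selected, collapse = "+") else "1"
  fit <- .quietGlm(as.formula(paste(".y ~", rhs)), d)
  warned <- attr(fit, "glm_warned")
  penalized <- FALSE
  sep <- warned || any(abs(coef(fit)[-1]) > 15, na.rm = TRUE)
  if (sep && length(selected)) {
    warning("possible separation in stepwise logistic fit; using ridge-penalized refit")
    X <- .designMatrix(table[, selected, drop = FALSE], template[names(template) %in% selected])
    fit <- glmnet::glmnet(X, as.numeric(labels), family = "binomial",
                          alpha = 0, lambda = 0.01)
    penalized <- TRUE
  }
  list(fit = fit, selected = selected, template = template, penalized = penalized)
}

#' Random forest classifier
#'
#' 500 trees, `sqrt(p)` candidate predictors per split; class probability is
#' the average of per-tree votes; impurity importances retained.
#'
#' @param table imputed, Unknown-encoded data.frame.
#' @param labels logical outcome.
#' @param seed integer seed.
#' @param ntree number of trees.
#' @return list with the `randomForest` fit and the factor `template`.
#' @export
fitRandomForest <- function(table, labels, seed = 1L, ntree = 500L) {
  template <- .factorTemplate(table)
  tab <- .applyFactorTemplate(table, template)
  set.seed(seed)
  fit <- randomForest::randomForest(x = tab,
                                    y = factor(as.integer(labels), levels = c(0, 1)),
                                    ntree = ntree, importance = TRUE)
  list(fit = fit, template = template)
}

#' Support vector machine on externally selected features
#'
#' Radial-basis SVM with Platt-type probability calibration; cost and gamma
#' are chosen by an internal 5-fold grid on the training data. The SVM has
#' no intrinsic variable selection, so `feature_list` (the positive-gain
#' features of a gradient-boosting fit) is required.
#'
#' @param table imputed, Unknown-encoded data.frame.
#' @param labels logical outcome.
#' @param feature_list original column names to use (mandatory).
#' @param seed integer seed.
#' @return list with the `svm` fit, `template`, selected `features` and the
#'   tuned hyperparameters.
#' @export
fitSVM <- function(table, labels, feature_list, seed = 1L) {
  if (missing(feature_list) || is.null(feature_list) || !length(feature_list))
    stop("fitSVM requires a feature list selected by gradient boosting")
  feature_list <- intersect(feature_list, names(table))
  tab <- table[, feature_list, drop = FALSE]
  template <- .factorTemplate(tab)
  X <- .designMatrix(tab, template)
  y <- factor(as.integer(labels), levels = c(0, 1))
  set.seed(seed)
  grid <- expand.grid(gamma = 1 / ncol(X) * c(0.5, 1, 2), cost = c(1, 10))
  errs <- vapply(seq_len(nrow(grid)), function(i) {
    m <- e1071::svm(X, y, kernel = "radial", gamma = grid$gamma[i],
                    cost = grid$cost[i], cross = 5)
    100 - m$tot.accuracy
  }, numeric(1))
  bi <- which.min(errs)
  set.seed(seed)
  fit <- e1071::svm(X, y, kernel = "radial", gamma = grid$gamma[bi],
                    cost = grid$cost[bi], probability = TRUE)
  list(fit = fit, template = template, features = feature_list,
       gamma = grid$gamma[bi], cost = grid$cost[bi])
}

#' Gradient boosting on the raw (missing-value) table
#'
#' XGBoost-style boosted trees consuming the raw table: categorical columns
#' (already "Unknown"-encoded) are one-hot expanded, continuous columns keep
#' their NA entries and the trees learn default split directions for them.
#' 300 rounds, depth 4, learning rate 0.1 with early stopping on an internal
#' stratified validation fold. Per-feature total gain is retained, both per
#' dummy column and aggregated per original variable.
#'
#' @param table raw data.frame (categoricals Unknown-encoded, continuous NA
#'   allowed).
#' @param labels logical outcome.
#' @param seed integer seed.
#' @param nrounds,max_depth,eta boosting hyperparameters.
#' @return list with the booster, `template`, per-variable `gain` and
#'   positive-gain `selected` variables.
#' @export
fitGradientBoosting <- function(table, labels, seed = 1L, nrounds = 300L,
                                max_depth = 4L, eta = 0.1) {
  template <- .factorTemplate(table)
  X <- .designMatrix(table, template)
  y <- as.numeric(labels)
  set.seed(seed)
  # internal stratified validation fold for early stopping
  idx1 <- which(y == 1); idx0 <- which(y == 0)
  val <- c(idx1[seq_len(max(1L, floor(length(idx1) / 5)))],
           idx0[seq_len(max(1L, floor(length(idx0) / 5)))])
  val <- sort(val)
  tr <- setdiff(seq_along(y), val)
  dtr <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr])
  dva <- xgboost::xgb.DMatrix(X[val, , drop = FALSE], label = y[val])
  params <- list(objective = "binary:logistic", max_depth = max_depth,
                 eta = eta, nthread = 1, seed = seed)
  fit <- xgboost::xgb.train(params = params, data = dtr, nrounds = nrounds,
                            evals = list(val = dva),
                            early_stopping_rounds = 20L, verbose = 0)
  imp <- xgboost::xgb.importance(model = fit)
  gain_dummy <- setNames(imp$Gain, imp$Feature)
  orig <- sub("=.*$", "", names(gain_dummy))
  gain <- tapply(gain_dummy, orig, sum)
  gain <- sort(c(gain), decreasing = TRUE)
  list(fit = fit, template = template, feature_names = colnames(X),
       gain = gain, gain_dummy = gain_dummy,
       selected = names(gain)[gain > 0])
}

#' Scaled importance report
#'
#' Converts raw per-feature importance (total gain for boosting, impurity
#' decrease for random forest) to the reporting scale: the most important
#' feature is set to exactly 1.0, all others are standardized by it, scores
#' are sorted descending, and scaled scores below 0.01 are omitted.
#'
#' @param model a [TrainedLevelModel-class] (tree family) or a named
#'   numeric vector of raw scores.
#' @return named numeric vector of scaled scores.
#' @export
importanceReport <- function(model) {
  raw <- if (is(model, "TrainedLevelModel")) model@importance else model
  if (is.null(raw) || !length(raw))
    stop("no importance scores available (tree families only)")
  raw <- raw[raw >= 0]
  sc <- sort(raw / max(raw), decreasing = TRUE)
  sc[sc >= 0.01]
}

#' Train one (family, level) model with its full data policy
#'
#' Applies the family-appropriate missing-data handling, variable
#' selection and fitting to a raw predictor table: Unknown encoding for
#' all; KNN-median imputation (state fitted here, on these rows only) for
#' logistic regression, random forest and SVM; raw missing values for
#' gradient boosting. The SVM first fits a gradient-boosting model to
#' obtain its feature list. The returned model carries everything needed
#' to score unseen raw rows via [predictModel()].
#'
#' @param family `"lr"`, `"rf"`, `"svm"` or `"xgb"`.
#' @param table raw predictor data.frame (as from [assembleLevel()]).
#' @param labels logical outcome.
#' @param level feature level (1, 2 or 3), recorded on the model.
#' @param seed integer seed.
#' @param k_impute neighbors for KNN imputation.
#' @return a [TrainedLevelModel-class] (cutoff not yet selected, NA).
#' @export
trainLevelModel <- function(family, table, labels, level = 1L, seed = 1L,
                            k_impute = 5L) {
  labels <- as.logical(labels)
  enc <- encodeUnknown(table)
  if (family == "xgb") {
    f <- fitGradientBoosting(enc, labels, seed = seed)
    return(new("TrainedLevelModel", family = "xgb", level = as.integer(level),
               fit = f$fit, featureList = f$feature_names, imputer = NULL,
               cutoff = NA_real_, importance = f$gain,
               extras = list(template = f$template, gain_dummy = f$gain_dummy,
                             selected = f$selected)))
  }
  imputer <- fitImputer(enc, k = k_impute)
  timp <- imputeTable(imputer, enc)
  if (family == "lr") {
    f <- fitStepwiseLogistic(timp, labels)
    new("TrainedLevelModel", family = "lr", level = as.integer(level),
        fit = f$fit, featureList = f$selected, imputer = imputer,
        cutoff = NA_real_, importance = NULL,
        extras = list(template = f$template, penalized = f$penalized))
  } else if (family == "rf") {
    f <- fitRandomForest(timp, labels, seed = seed)
    imp <- randomForest::importance(f$fit)[, "MeanDecreaseGini"]
    new("TrainedLevelModel", family = "rf", level = as.integer(level),
        fit = f$fit, featureList = names(timp), imputer = imputer,
        cutoff = NA_real_, importance = imp,
        extras = list(template = f$template))
  } else if (family == "svm") {
    xg <- fitGradientBoosting(enc, labels, seed = seed)
    f <- fitSVM(timp, labels, feature_list = xg$selected, seed = seed)
    new("TrainedLevelModel", family = "svm", level = as.integer(level),
        fit = f$fit, featureList = f$features, imputer = imputer,
        cutoff = NA_real_, importance = NULL,
        extras = list(template = f$template, gamma = f$gamma, cost = f$cost,
                      xgb_gain = xg$gain))
  } else stop("unknown family: ", family)
}

#' Score raw rows with a trained level model
#'
#' Applies the model's own deployment policy (Unknown encoding, the frozen
#' training imputation state, frozen factor levels) and returns P(LVO) in
#' \[0,1\] for each row.
#'
#' @param model a [TrainedLevelModel-class].
#' @param table raw predictor data.frame with the training columns.
#' @return numeric vector of probabilities.
#' @export
predictModel <- function(model, table) {
  enc <- encodeUnknown(table)
  if (model@family == "xgb") {
    X <- .designMatrix(enc, model@extras$template)
    X <- X[, model@featureList, drop = FALSE]
    return(as.numeric(predict(model@fit, xgboost::xgb.DMatrix(X))))
  }
  timp <- imputeTable(model@imputer, enc)
  if (model@family == "lr") {
    if (model@extras$penalized) {
      sel <- model@featureList
      X <- .designMatrix(timp[, sel, drop = FALSE],
                         model@extras$template[names(model@extras$template) %in% sel])
      return(as.numeric(predict(model@fit, X, type = "response")))
    }
    d <- .applyFactorTemplate(timp, model@extras$template)
    return(as.numeric(predict(model@fit, newdata = d, type = "response")))
  }
  if (model@family == "rf") {
    d <- .applyFactorTemplate(timp, model@extras$template)
    return(as.numeric(predict(model@fit, d, type = "prob")[, "1"]))
  }
  if (model@family == "svm") {
    X <- .designMatrix(timp[, model@featureList, drop = FALSE], model@extras$template)
    pr <- predict(model@fit, X, probability = TRUE)
    return(as.numeric(attr(pr, "probabilities")[, "1"]))
  }
  stop("unknown family")
}
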