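# End-to-end driver: synthetic cohort -> phantoms -> preprocessing ->
# segmentation training -> deep features -> three nested model levels x
# four families -> cutoff selection -> held-out metric grid.

# Feature extraction over a plain list of (already cropped) patches with a
# provenance frame; shared by extractDeepFeatures and the orchestrator's
# memory-lean path.
.extractFromPatchList <- function(net, pts, prov, pid, threshold = 0.5) {
  slices <- unique(prov$slice)
  areas <- vapply(slices, function(s) {
    ii <- which(prov$slice == s)
    sum(vapply(ii, function(i)
      sum(predictSegNet(net, pts[[i]]) >= threshold), numeric(1)))
  }, numeric(1))
  sel <- selectRepresentativeSlice(areas)
  ii <- which(prov$slice == slices[sel])
  f <- do.call(pmax, lapply(ii, function(i) segFeatureHead(net, pts[[i]])))
  new("DeepFeatures", patientId = pid, values = f, sourceSlice = sel)
}

#' Generate and preprocess the imaging arm of a cohort
#'
#' For every patient, generates a phantom study keyed by the patient id
#' (so regeneration is independent of cohort ordering), runs the full
#' preprocessing pipeline, and retains the centre-cropped patches (and,
#' for later segmentation training, the aligned truth-mask patches).
#'
#' @param cohort cohort data.frame.
#' @param phantom_config a [phantomConfig()].
#' @param preprocess_config a [preprocessConfig()].
#' @param net_config a [segNetConfig()]; patches are cropped to its input
#'   size.
#' @return list per patient: `patches`, `masks`, `prov`, `has_sign`.
#' @export
cohortImaging <- function(cohort, phantom_config = phantomConfig(),
                          preprocess_config = preprocessConfig(),
                          net_config = segNetConfig()) {
  out <- vector("list", nrow(cohort))
  names(out) <- cohort$id
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$id[i]
    ph <- generatePhantom(phantom_config, label_lvo = cohort$lvo[i],
                          seed = substreamSeed(phantom_config$seed, id), id = id)
    pp <- preprocessStudy(ph, preprocess_config)
    pts <- lapply(patches(pp$stack), .cropMask, config = net_config)
    msk <- lapply(pp$masks, .cropMask, config = net_config)
    out[[i]] <- list(patches = pts, masks = msk,
                     prov = provenance(pp$stack), has_sign = hasSign(ph))
  }
  out
}

#' Run the full three-level evaluation pipeline
#'
#' Generates (or accepts) a cohort, splits it into stratified training and
#' test groups, builds the imaging arm when Level 3 is requested (phantoms,
#' preprocessing, segmentation training on the training split only, deep
#' feature extraction, t-test screening on the training split only), then
#' for every requested (level, family) cell fits the model on the training
#' split, selects its probability cutoff by stratified 10-fold
#' cross-validated Youden index, and evaluates exactly once on the held-out
#' test split. No test-split information reaches any training-time
#' decision.
#'
#' @param config a [runConfig()].
#' @param cohort optional pre-generated cohort (defaults to
#'   `generateCohort(config$cohort_config)`).
#' @param split optional list with integer row indices `train`, `test`.
#' @param segnet optional pre-trained [SegNet-class]; when supplied,
#'   segmentation training is skipped and features are extracted with it.
#' @param imaging optional precomputed [cohortImaging()] result.
#' @return list with `report` (one row per cell), `metrics` (list of
#'   [MetricsReport-class]), `models`, `artifacts` (screen indices, split,
#'   deep feature matrix, segnet) and `config`.
#' @export
runPipeline <- function(config = runConfig(), cohort = NULL, split = NULL,
                        segnet = NULL, imaging = NULL) {
  stopifnot(inherits(config, "runConfig"))
  if (is.null(cohort)) cohort <- generateCohort(config$cohort_config)
  n <- nrow(cohort)
  if (is.null(split)) {
    set.seed(substreamSeed(config$seed, "split"))
    frac <- config$n_train / config$n_patients
    tr <- integer(0)
    for (cl in c(TRUE, FALSE)) {
      idx <- which(cohort$lvo == cl)
      tr <- c(tr, sample(idx, round(frac * length(idx))))
    }
    split <- list(train = sort(tr), test = setdiff(seq_len(n), tr))
  }
  labels <- as.logical(cohort$lvo)
  deep <- NULL; screen <- NULL
  if (3L %in% config$levels) {
    net_config <- segNetConfig(profile = config$profile)
    if (is.null(imaging))
      imaging <- cohortImaging(cohort, config$phantom_config,
                               config$preprocess_config, net_config)
    if (is.null(segnet)) {
      tr_ids <- sort(cohort$id[split$train])
      # cap the training pool; keep sign-positive patients preferentially --
      # positive-patch diversity is what makes desk-scale training stable
      cap <- config$seg_max_patients
      if (length(tr_ids) > cap) {
        sgn <- vapply(tr_ids, function(id) imaging[[id]]$has_sign, logical(1))
        tr_ids <- c(tr_ids[sgn], tr_ids[!sgn])[seq_len(cap)]
        tr_ids <- sort(tr_ids)
      }
      # per patient: the lesion patches (when present) plus two background
      # patches, rather than all 12 -- keeps the pool positive-rich
      pool_p <- list(); pool_m <- list()
      for (id in tr_ids) {
        msum <- vapply(imaging[[id]]$masks, sum, numeric(1))
        posk <- which(msum > 0)
        negk <- setdiff(seq_along(msum), posk)[1:2]
        kk <- c(posk, negk)
        pool_p <- c(pool_p, imaging[[id]]$patches[kk])
        pool_m <- c(pool_m, imaging[[id]]$masks[kk])
      }
      segnet <- trainSegmenter(pool_p, pool_m, net_config,
                               segTrainConfig(epochs = config$seg_epochs,
                                              seed = substreamSeed(config$seed, "segtrain")))
    }
    feats <- lapply(cohort$id, function(id)
      .extractFromPatchList(segnet, imaging[[id]]$patches, imaging[[id]]$prov, id))
    deep <- deepFeatureMatrix(feats)
    screen <- ttestScreen(deep[split$train, , drop = FALSE], labels[split$train])
  }
  report <- NULL; metrics <- list(); models <- list()
  for (lev in sort(config$levels)) {
    tab <- assembleLevel(lev, cohort, deep_features = deep,
                         selected = screen$indices)
    for (fam in config$families) {
      key <- sprintf("L%d_%s", lev, fam)
      cv <- selectCutoffCV(fam, tab[split$train, , drop = FALSE],
                           labels[split$train],
                           cutoffConfig(seed = substreamSeed(config$seed,
                                                            paste0("cv-", key))),
                           level = lev)
      m <- trainLevelModel(fam, tab[split$train, , drop = FALSE],
                           labels[split$train], level = lev,
                           seed = substreamSeed(config$seed, paste0("fit-", key)))
      m@cutoff <- cv$cutoff
      sc <- predictModel(m, tab[split$test, , drop = FALSE])
      rep <- confusionMetrics(labels[split$test], sc, cv$cutoff)
      metrics[[key]] <- rep
      models[[key]] <- m
      report <- rbind(report, data.frame(
        level = lev, family = fam,
        data = if (fam == "xgb") "Raw" else "Imputed",
        youden = rep@youden, accuracy = rep@accuracy, recall = rep@recall,
        specificity = rep@specificity, f1 = rep@f1, auc = rep@auc,
        cutoff = cv$cutoff, stringsAsFactors = FALSE))
    }
  }
  list(report = report, metrics = metrics, models = models,
       artifacts = list(split = split, screen = screen, deep = deep,
                        segnet = segnet, imaging = imaging),
       config = config)
}
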