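# Synthetic tabular cohort generation.
#
# Records are drawn class-conditionally: the LVO label first (Bernoulli at
# the configured prevalence), then each variable from its class-conditional
# marginal. Structurally linked variables are drawn as blocks so each record
# is internally consistent: side-specific weakness comes from a single
# both/left/right/none pattern, smoking from a never/current/ex trichotomy,
# and the GCS total is the sum of subscales drawn first. Missingness is part
# of the data model: categorical variables carry an "Unknown" mass (encoded
# as NA in the raw cohort and surfaced as a literal level by
# [encodeUnknown()]), continuous variables an NA mass.

.truncNormInt <- function(n, mean, sd, range) {
  x <- round(rnorm(n, mean, sd))
  pmin(pmax(x, range[1]), range[2])
}

.truncNorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pmin(pmax(rnorm(n, mean, sd), lower), upper)
}

#' Generate a synthetic stroke cohort
#'
#' Draws `n_patients` records under the class-conditional marginal model in
#' `config$feature_spec`. Deterministic given `config$seed`. The returned
#' data.frame has one row per patient: `id`, logical `lvo`, then the Level-1
#' and Level-2 variables; categorical columns are character with NA for
#' unrecorded ("Unknown") entries, continuous columns numeric with NA where
#' unmeasured.
#'
#' @param config a [cohortConfig()].
#' @return a data.frame with attribute `level_map` (named character vector
#'   giving the feature level of every variable column).
#' @examples
#' coh <- generateCohort(cohortConfig(n_patients = 50, seed = 7))
#' table(coh$lvo)
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "cohortConfig"))
  n <- config$n_patients
  spec <- config$feature_spec
  cols <- .cohortColumns(spec)
  if (n == 0L) {
    empty <- c(list(id = character(0), lvo = logical(0)),
               lapply(cols$type, function(tp)
                 if (tp == "continuous") numeric(0) else character(0)))
    df <- as.data.frame(empty, stringsAsFactors = FALSE)
    names(df) <- c("id", "lvo", cols$name)
    attr(df, "level_map") <- setNames(cols$level, cols$name)
    return(df)
  }
  set.seed(substreamSeed(config$seed, "cohort"))
  lvo <- runif(n) < config$lvo_prevalence
  cls <- ifelse(lvo, 1L, 2L)  # index into (lvo, nolvo) pairs
  out <- list(id = sprintf("P%04d", seq_len(n)), lvo = lvo)

  for (nm in names(spec)) {
    fs <- spec[[nm]]
    if (fs$type == "continuous") {
      mu <- fs$mean[cls]; sdv <- fs$sd[cls]
      x <- .truncNorm(n, mu, sdv, fs$lower, fs$upper)
      if (isTRUE(fs$integer)) x <- round(x)
      x[runif(n) < fs$p_missing[cls]] <- NA_real_
      out[[nm]] <- x
    } else if (fs$type == "categorical") {
      p <- rbind(fs$p_lvo, fs$p_nolvo)
      lev <- fs$levels
      x <- vapply(seq_len(n), function(i) sample(lev, 1L, prob = p[cls[i], ]),
                  character(1))
      # a literal "Unknown" level in the spec is stored as NA (unrecorded)
      x[x == "Unknown"] <- NA_character_
      out[[nm]] <- x
    } else if (fs$type == "side_pattern") {
      p <- rbind(fs$p_lvo, fs$p_nolvo)
      pat <- vapply(seq_len(n), function(i)
        sample(fs$levels, 1L, prob = p[cls[i], ]), character(1))
      any_w <- ifelse(pat == "None", "No", "Yes")
      left <- ifelse(pat %in% c("Both", "Left"), "Yes", "No")
      right <- ifelse(pat %in% c("Both", "Right"), "Yes", "No")
      unk <- runif(n) < fs$p_unknown[cls]
      any_w[unk] <- NA; left[unk] <- NA; right[unk] <- NA
      out[[nm]] <- any_w
      out[[paste0("left_", nm)]] <- left
      out[[paste0("right_", nm)]] <- right
    } else if (fs$type == "smoking") {
      p <- rbind(fs$p_lvo, fs$p_nolvo)
      st <- vapply(seq_len(n), function(i)
        sample(c("never", "current", "ex"), 1L, prob = p[cls[i], ]), character(1))
      smoker <- ifelse(st == "never", "No", "Yes")
      cur <- ifelse(st == "current", "Yes", "No")
      ex <- ifelse(st == "ex", "Yes", "No")
      unk <- runif(n) < fs$p_unknown[cls]
      smoker[unk] <- NA; cur[unk] <- NA; ex[unk] <- NA
      out$smoker <- smoker
      out$current_smoker <- cur
      out$ex_smoker <- ex
    } else if (fs$type == "gcs") {
      sub <- matrix(NA_real_, n, 3)
      ranges <- list(fs$eye$range, fs$verbal$range, fs$motor$range)
      parts <- list(fs$eye, fs$verbal, fs$motor)
      for (j in 1:3) {
        pj <- parts[[j]]
        sd_l <- .sdFromCI(pj$ci_l, fs$n_obs[["lvo"]])
        sd_n <- .sdFromCI(pj$ci_n, fs$n_obs[["nolvo"]])
        mu <- pj$mean[cls]; sdv <- c(sd_l, sd_n)[cls]
        sub[, j] <- .truncNormInt(n, mu, sdv, ranges[[j]])
      }
      total <- rowSums(sub)
      sub_missing <- runif(n) < fs$p_sub_missing[cls]
      tot_missing <- sub_missing & (runif(n) < fs$p_total_missing_given_sub[cls])
      sub[sub_missing, ] <- NA
      total[tot_missing] <- NA
      out$gcs <- total
      out$gcs_eye <- sub[, 1]; out$gcs_verbal <- sub[, 2]; out$gcs_motor <- sub[, 3]
    } else if (fs$type == "bp") {
      miss <- runif(n) < fs$p_missing[cls]
      for (v in c("dbp", "sbp")) {
        pj <- fs[[v]]
        sd_l <- .sdFromCI(pj$ci_l, fs$n_obs[["lvo"]])
        sd_n <- .sdFromCI(pj$ci_n, fs$n_obs[["nolvo"]])
        x <- .truncNorm(n, pj$mean[cls], c(sd_l, sd_n)[cls], lower = 30)
        x[miss] <- NA
        out[[v]] <- x
      }
    } else stop("unknown feature_spec type: ", fs$type)
  }
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  attr(df, "level_map") <- setNames(cols$level, cols$name)
  df
}

# Expand the spec into the flat column roster (name, type, level).
.cohortColumns <- function(spec) {
  name <- character(0); type <- character(0); level <- character(0)
  add <- function(nm, tp, lv) {
    name <<- c(name, nm); type <<- c(type, tp); level <<- c(level, lv)
  }
  for (nm in names(spec)) {
    fs <- spec[[nm]]
    switch(fs$type,
      continuous = add(nm, "continuous", fs$level),
      categorical = add(nm, "categorical", fs$level),
      side_pattern = {
        add(nm, "categorical", fs$level)
        add(paste0("left_", nm), "categorical", fs$level)
        add(paste0("right_", nm), "categorical", fs$level)
      },
      smoking = {
        add("smoker", "categorical", fs$level)
        add("current_smoker", "categorical", fs$level)
        add("ex_smoker", "categorical", fs$level)
      },
      gcs = {
        add("gcs", "continuous", fs$level)
        add("gcs_eye", "continuous", fs$level)
        add("gcs_verbal", "continuous", fs$level)
        add("gcs_motor", "continuous", fs$level)
      },
      bp = {
        add("dbp", "continuous", fs$level)
        add("sbp", "continuous", fs$level)
      })
  }
  list(name = name, type = type, level = level)
}

#' Column roster of a cohort by feature level
#'
#' @param cohort a cohort data.frame from [generateCohort()] or
#'   [readCohortCSV()].
#' @param level `"1"` or `"2"`; Level-2 includes Level-1 columns.
#' @return character vector of column names.
#' @export
levelColumns <- function(cohort, level = c("2", "1")) {
  level <- match.arg(level)
  lm <- attr(cohort, "level_map")
  if (is.null(lm)) stop("cohort has no level_map attribute")
  if (level == "1") names(lm)[lm == "1"] else names(lm)
}

#' Write / read a cohort as CSV
#'
#' Plain one-header-row CSV; empty cells are missing values. Continuous NA
#' round-trips as an empty cell; unrecorded categoricals are written as the
#' literal level `"Unknown"` and read back as NA, so a round trip preserves
#' the cohort (and the Unknown/NA identification).
#'
#' @param cohort cohort data.frame.
#' @param path file path.
#' @return `writeCohortCSV` returns `path` invisibly; `readCohortCSV`
#'   returns the cohort data.frame with its `level_map` attribute rebuilt.
#' @export
writeCohortCSV <- function(cohort, path) {
  out <- cohort
  lm <- attr(cohort, "level_map")
  for (nm in names(out)) {
    if (is.character(out[[nm]]) && nm != "id")
      out[[nm]][is.na(out[[nm]])] <- "Unknown"
  }
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeCohortCSV
#' @export
readCohortCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  df$lvo <- as.logical(df$lvo)
  for (nm in names(df)) {
    if (is.character(df[[nm]]) && nm != "id")
      df[[nm]][df[[nm]] == "Unknown"] <- NA_character_
  }
  cols <- .cohortColumns(defaultFeatureSpec())
  keep <- cols$name %in% names(df)
  attr(df, "level_map") <- setNames(cols$level[keep], cols$name[keep])
  df
}
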