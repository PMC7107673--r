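# Shared fixtures, built once per test session and cached.

.fx <- new.env(parent = emptyenv())

# A phantom study with a guaranteed lesion, plus its preprocessed form.
fxSignedStudy <- function() {
  if (is.null(.fx$signed)) {
    cfg <- phantomConfig(p_sign_given_lvo = 1, seed = 101L)
    ph <- generatePhantom(cfg, label_lvo = TRUE, seed = 101L, id = "FX01")
    pp <- preprocessStudy(ph, preprocessConfig())
    .fx$signed <- list(config = cfg, study = ph, pre = pp)
  }
  .fx$signed
}

# Synthetic windowed dot patches (lesion-like bright dot on soft-tissue
# noise), already at the tiny network input size; cheap stand-ins for
# preprocessed ROI patches in unit tests of the network machinery.
fxDotPatch <- function(sign, seed, n = 64L) {
  set.seed(seed)
  p <- matrix(pmax(rnorm(n * n, 30, 1.5), 0), n, n)
  m <- matrix(0L, n, n)
  if (sign) {
    r <- sample(8:(n - 7), 1); c <- sample(8:(n - 7), 1)
    rad <- runif(1, 2, 5)
    rr <- (r - 6):(r + 6); cc <- (c - 6):(c + 6)
    d2 <- outer((rr - r)^2, (cc - c)^2, "+")
    sel <- d2 <= rad^2
    p[rr, cc][sel] <- 60
    m[rr, cc][sel] <- 1L
  }
  list(patch = p, mask = m)
}

fxDotPool <- function(n_total = 40L, pos_every = 4L, n = 64L) {
  pool <- lapply(seq_len(n_total), function(i)
    fxDotPatch(i %% pos_every == 0, seed = 5000 + i, n = n))
  pats <- lapply(pool, `[[`, "patch")
  msks <- lapply(pool, `[[`, "mask")
  names(pats) <- names(msks) <- sprintf("dot%03d", seq_len(n_total))
  list(patches = pats, masks = msks)
}

# A quickly trained tiny segmenter over synthetic dot patches, reused by
# feature-extraction tests.
fxTinyNet <- function() {
  if (is.null(.fx$tinynet)) {
    pool <- fxDotPool(32L, pos_every = 3L)
    .fx$tinynet <- trainSegmenter(pool$patches, pool$masks, segNetConfig("tiny"),
                                  segTrainConfig(epochs = 6, seed = 21))
  }
  .fx$tinynet
}

diceScore <- function(prob, truth, threshold = 0.5) {
  p <- prob >= threshold
  denom <- sum(p) + sum(truth)
  if (denom == 0) return(1)
  2 * sum(p & truth == 1) / denom
}

# Build an ROIStack around 12 given 128 x 128 patches.
fxStack <- function(patches, id = "FX") {
  prov <- data.frame(slice = rep(4:9, each = 2),
                     hemisphere = rep(c("A", "B"), 6), stringsAsFactors = FALSE)
  names(patches) <- sprintf("%s_s%02d_%s", id, prov$slice, prov$hemisphere)
  new("ROIStack", patientId = id, patches = patches, provenance = prov)
}
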