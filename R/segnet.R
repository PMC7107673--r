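# Encoder-decoder fully convolutional network for hyperdense-MCA-sign
# segmentation, written as vectorized R over BLAS matrix products. A 3x3
# "same" convolution is one matrix product of the C++-built im2col matrix
# (H*W, 9*Cin) against the flattened kernel (9*Cin, Cout); the backward
# pass reuses the cached im2col matrix and its col2im adjoint, which keeps
# the network exact, deterministic and single-threaded reproducible.
#
# Architecture: depth D encoder stages (3x3 conv + ReLU + 2x2 max pool,
# channels doubling from base), a 3x3 bottleneck conv (ReLU) whose maps are
# reduced by a global max pool into the patient feature vector, then D
# decoder stages (nearest-neighbour 2x upsampling, skip concatenation with
# the matching encoder activation, 3x3 conv + ReLU) and a 1x1 conv +
# sigmoid pixel classifier.

.relu <- function(x) { x[x < 0] <- 0; x }
.sigmoid <- function(z) 1 / (1 + exp(-z))

# 3x3 convolutions run as a single BLAS product against the C++ im2col
# matrix; xcol may be passed in (training caches it between the forward and
# backward pass of a sample).
.convFwd <- function(x, W, b, xcol = NULL) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; Cin <- d[3]
  K <- dim(W)[1]; Cout <- dim(W)[4]
  if (K == 1L) {
    Wk <- array(W[1, 1, , ], dim = c(Cin, Cout))
    ymat <- matrix(x, H * Wd, Cin) %*% Wk
  } else {
    if (is.null(xcol)) xcol <- .im2col3x3_cpp(x, H, Wd, Cin)
    ymat <- xcol %*% matrix(W, 9L * Cin, Cout)
  }
  ymat <- ymat + rep(b, each = H * Wd)
  array(ymat, dim = c(H, Wd, Cout))
}

.convBwd <- function(dy_arr, x, W, xcol = NULL) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; Cin <- d[3]
  K <- dim(W)[1]; Cout <- dim(W)[4]
  dym <- matrix(dy_arr, H * Wd, Cout)
  db <- colSums(dym)
  if (K == 1L) {
    Wk <- array(W[1, 1, , ], dim = c(Cin, Cout))
    dW <- array(crossprod(matrix(x, H * Wd, Cin), dym), dim = dim(W))
    dx <- array(dym %*% t(Wk), dim = c(H, Wd, Cin))
    return(list(dx = dx, dW = dW, db = db))
  }
  if (is.null(xcol)) xcol <- .im2col3x3_cpp(x, H, Wd, Cin)
  Wm <- matrix(W, 9L * Cin, Cout)
  dW <- array(crossprod(xcol, dym), dim = dim(W))
  dx <- .col2im3x3_cpp(dym %*% t(Wm), H, Wd, Cin)
  list(dx = dx, dW = dW, db = db)
}

.poolFwd <- function(x) {
  d <- dim(x); i1 <- seq(1L, d[1], 2L); j1 <- seq(1L, d[2], 2L)
  s11 <- x[i1, j1, , drop = FALSE]; s21 <- x[i1 + 1L, j1, , drop = FALSE]
  s12 <- x[i1, j1 + 1L, , drop = FALSE]; s22 <- x[i1 + 1L, j1 + 1L, , drop = FALSE]
  pmax(s11, s21, s12, s22)
}

.poolBwd <- function(dy_arr, x, y) {
  d <- dim(x); i1 <- seq(1L, d[1], 2L); j1 <- seq(1L, d[2], 2L)
  dx <- array(0, dim = d)
  for (off in list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))) {
    ii <- i1 + off[1]; jj <- j1 + off[2]
    sub <- x[ii, jj, , drop = FALSE]
    # ties share the gradient (all argmax positions receive it)
    dx[ii, jj, ] <- dx[ii, jj, , drop = FALSE] + dy_arr * (sub == y)
  }
  dx
}

.upFwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , drop = FALSE]
}

.upBwd <- function(dy_arr) {
  d <- dim(dy_arr); i1 <- seq(1L, d[1], 2L); j1 <- seq(1L, d[2], 2L)
  dy_arr[i1, j1, , drop = FALSE] + dy_arr[i1 + 1L, j1, , drop = FALSE] +
    dy_arr[i1, j1 + 1L, , drop = FALSE] + dy_arr[i1 + 1L, j1 + 1L, , drop = FALSE]
}

.concat3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), dim = c(da[1], da[2], da[3] + db[3]))
}

# Channel schedule: encoder stages double from base; bottleneck as configured.
.channelPlan <- function(config) {
  ch <- config$base_channels * 2^(seq_len(config$depth) - 1L)
  list(enc = ch, bottleneck = config$bottleneck_channels)
}

#' Build an untrained segmentation network
#'
#' Initializes the encoder-decoder FCN described in [segNetConfig()] with
#' He-scaled Gaussian weights. The forward pass maps an
#' `input_size x input_size` patch to a per-pixel probability map of the
#' same size; the feature head exposes the global-max-pooled bottleneck
#' vector of length `bottleneck_channels`.
#'
#' @param config a [segNetConfig()].
#' @param seed integer seed for weight initialization.
#' @return a [SegNet-class].
#' @export
buildSegNet <- function(config = segNetConfig(), seed = 1L) {
  stopifnot(inherits(config, "segNetConfig"))
  if (config$input_size %% 2^config$depth != 0)
    stop("input_size must be divisible by 2^depth")
  set.seed(seed)
  plan <- .channelPlan(config)
  mk <- function(k, cin, cout)
    list(W = array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
                   dim = c(k, k, cin, cout)),
         b = numeric(cout))
  params <- list()
  cin <- 1L
  for (i in seq_len(config$depth)) {
    params[[paste0("enc", i)]] <- mk(3L, cin, plan$enc[i])
    cin <- plan$enc[i]
  }
  params$bott <- mk(3L, cin, plan$bottleneck)
  prev <- plan$bottleneck
  for (i in rev(seq_len(config$depth))) {
    params[[paste0("dec", i)]] <- mk(3L, prev + plan$enc[i], plan$enc[i])
    prev <- plan$enc[i]
  }
  params$out <- mk(1L, prev, 1L)
  fp <- sprintf("segnet-d%d-b%d-k%d-i%d", config$depth, config$base_channels,
                config$bottleneck_channels, config$input_size)
  new("SegNet", config = unclass(config), params = params,
      state = list(), trained = FALSE, fingerprint = fp)
}

# Centre-crop a patch to the network input size and scale to [0,1].
.prepPatch <- function(patch, config) {
  n <- config$input_size
  d <- dim(patch)
  if (d[1] != n || d[2] != n) {
    r0 <- (d[1] - n) %/% 2L; c0 <- (d[2] - n) %/% 2L
    patch <- patch[(r0 + 1L):(r0 + n), (c0 + 1L):(c0 + n)]
  }
  patch / config$intensity_scale
}

.cropMask <- function(mask, config) {
  n <- config$input_size
  d <- dim(mask)
  if (d[1] != n || d[2] != n) {
    r0 <- (d[1] - n) %/% 2L; c0 <- (d[2] - n) %/% 2L
    mask <- mask[(r0 + 1L):(r0 + n), (c0 + 1L):(c0 + n)]
  }
  mask
}

# Full forward pass; with cache = TRUE all intermediates needed by the
# backward pass are retained. features_only skips the decoder.
.segFwd <- function(net, x01, cache = FALSE, features_only = FALSE) {
  cfg <- net$config; p <- net$params
  D <- cfg$depth
  a <- array(x01, dim = c(dim(x01)[1], dim(x01)[2], 1L))
  cc <- list(input = a)
  acts <- vector("list", D)
  colOf <- function(x) if (cache) .im2col3x3_cpp(x, dim(x)[1], dim(x)[2], dim(x)[3]) else NULL
  for (i in seq_len(D)) {
    xcol <- colOf(a)
    z <- .convFwd(a, p[[paste0("enc", i)]]$W, p[[paste0("enc", i)]]$b, xcol = xcol)
    r <- .relu(z)
    acts[[i]] <- r
    pooled <- .poolFwd(r)
    if (cache) { cc[[paste0("enc_in", i)]] <- a; cc[[paste0("enc_col", i)]] <- xcol
                 cc[[paste0("enc_z", i)]] <- z
                 cc[[paste0("enc_r", i)]] <- r; cc[[paste0("pool", i)]] <- pooled }
    a <- pooled
  }
  xcol <- colOf(a)
  zb <- .convFwd(a, p$bott$W, p$bott$b, xcol = xcol)
  rb <- .relu(zb)
  if (cache) { cc$bott_in <- a; cc$bott_col <- xcol; cc$bott_z <- zb; cc$bott_r <- rb }
  feats <- apply(rb, 3L, max)
  if (features_only)
    return(list(features = feats))
  u <- rb
  for (i in rev(seq_len(D))) {
    up <- .upFwd(u)
    cat_in <- .concat3(up, acts[[i]])
    xcol <- colOf(cat_in)
    z <- .convFwd(cat_in, p[[paste0("dec", i)]]$W, p[[paste0("dec", i)]]$b, xcol = xcol)
    r <- .relu(z)
    if (cache) { cc[[paste0("dec_up", i)]] <- up; cc[[paste0("dec_in", i)]] <- cat_in
                 cc[[paste0("dec_col", i)]] <- xcol
                 cc[[paste0("dec_z", i)]] <- z; cc[[paste0("dec_r", i)]] <- r }
    u <- r
  }
  zo <- .convFwd(u, p$out$W, p$out$b)
  prob <- .sigmoid(zo[, , 1L])
  if (cache) { cc$out_in <- u; cc$prob <- prob }
  list(prob = prob, features = feats, cache = if (cache) cc else NULL)
}

# Backward pass from dL/dprob; returns gradients in the params layout.
.segBwd <- function(net, dprob, cc) {
  cfg <- net$config; p <- net$params
  D <- cfg$depth
  prob <- cc$prob
  dz <- dprob * prob * (1 - prob)
  dz <- array(dz, dim = c(dim(dz)[1], dim(dz)[2], 1L))
  g <- list()
  bw <- .convBwd(dz, cc$out_in, p$out$W)
  g$out <- list(W = bw$dW, b = bw$db)
  du <- bw$dx
  for (i in seq_len(D)) {
    du <- du * (cc[[paste0("dec_z", i)]] > 0)
    bw <- .convBwd(du, cc[[paste0("dec_in", i)]], p[[paste0("dec", i)]]$W,
                   xcol = cc[[paste0("dec_col", i)]])
    g[[paste0("dec", i)]] <- list(W = bw$dW, b = bw$db)
    nup <- dim(cc[[paste0("dec_up", i)]])[3]
    dcat <- bw$dx
    dup <- dcat[, , seq_len(nup), drop = FALSE]
    # skip-connection gradient flows back into the encoder activation
    g[[paste0("skip", i)]] <- dcat[, , (nup + 1L):dim(dcat)[3], drop = FALSE]
    du <- .upBwd(dup)
  }
  du <- du * (cc$bott_z > 0)
  bw <- .convBwd(du, cc$bott_in, p$bott$W, xcol = cc$bott_col)
  g$bott <- list(W = bw$dW, b = bw$db)
  dpool <- bw$dx
  for (i in rev(seq_len(D))) {
    dr <- .poolBwd(dpool, cc[[paste0("enc_r", i)]], cc[[paste0("pool", i)]])
    dr <- dr + g[[paste0("skip", i)]]
    g[[paste0("skip", i)]] <- NULL
    dzi <- dr * (cc[[paste0("enc_z", i)]] > 0)
    bw <- .convBwd(dzi, cc[[paste0("enc_in", i)]], p[[paste0("enc", i)]]$W,
                   xcol = cc[[paste0("enc_col", i)]])
    g[[paste0("enc", i)]] <- list(W = bw$dW, b = bw$db)
    dpool <- bw$dx
  }
  g
}

#' Tversky loss between a probability map and a binary truth map
#'
#' Soft (probabilistic) Tversky index
#' `TI = (TP + eps) / (TP + alpha FP + beta FN + eps)` with
#' `TP = sum(p t)`, `FP = sum(p (1-t))`, `FN = sum((1-p) t)`; the loss is
#' `1 - TI`. With `alpha = beta = 0.5` this reduces to the soft Dice loss.
#' Asymmetric weights let training penalize missed lesion pixels
#' (`beta`) harder than false alarms (`alpha`), the usual regime for very
#' small lesions.
#'
#' @param pred numeric array of probabilities in \[0,1\].
#' @param truth binary array of the same shape.
#' @param alpha false-positive weight.
#' @param beta false-negative weight.
#' @param eps smoothing constant.
#' @return scalar loss in \[0,1\].
#' @export
tverskyLoss <- function(pred, truth, alpha = 0.3, beta = 0.7, eps = 1e-6) {
  if (!identical(dim(pred), dim(truth)) &&
      !(is.null(dim(pred)) && is.null(dim(truth)) && length(pred) == length(truth)))
    stop("pred and truth must have identical shapes")
  tp <- sum(pred * truth)
  fp <- sum(pred * (1 - truth))
  fn <- sum((1 - pred) * truth)
  1 - (tp + eps) / (tp + alpha * fp + beta * fn + eps)
}

# dL/dpred of the Tversky loss, elementwise.
.tverskyGrad <- function(pred, truth, alpha, beta, eps = 1e-6) {
  tp <- sum(pred * truth)
  fp <- sum(pred * (1 - truth))
  fn <- sum((1 - pred) * truth)
  num <- tp + eps
  den <- tp + alpha * fp + beta * fn + eps
  dden <- truth + alpha * (1 - truth) - beta * truth
  -(truth * den - num * dden) / den^2
}

#' Hard-negative mining over a pool of patch losses
#'
#' Keeps every lesion-positive patch and, among lesion-free patches, only
#' the `ratio * n_positive` with the highest current loss (all of them if
#' fewer exist). When the pool contains no positive patch, the `ceiling(ratio)`
#' hardest negatives are kept so optimization can still proceed.
#'
#' @param losses numeric vector of per-patch losses.
#' @param is_positive logical vector, TRUE where the patch's mask is
#'   nonempty.
#' @param ratio negatives kept per positive.
#' @return integer indices of the retained patches (positives first, then
#'   negatives by decreasing loss).
#' @export
mineHardNegatives <- function(losses, is_positive, ratio = 3) {
  stopifnot(length(losses) == length(is_positive), length(losses) >= 1)
  pos <- which(is_positive)
  neg <- which(!is_positive)
  n_keep <- if (length(pos)) floor(ratio * length(pos)) else ceiling(ratio)
  neg_kept <- neg[order(losses[neg], decreasing = TRUE)][seq_len(min(n_keep, length(neg)))]
  c(pos, neg_kept)
}

#' Train the segmentation network
#'
#' Adam optimization of the Tversky loss with epoch-level hard-negative
#' mining: each epoch the current loss of every patch is computed, the pool
#' is reduced by [mineHardNegatives()], and the retained patches are
#' shuffled into minibatches. Patches larger than the network input are
#' centre-cropped; intensities are scaled by `config$intensity_scale`.
#' Training is deterministic given `train_config$seed` (patches are
#' canonicalized by name before the seeded shuffle, so the caller's
#' ordering is irrelevant).
#'
#' Two stabilizers guard against the all-background collapse that a small
#' lesion prior invites: the weights with the best mean positive-patch loss
#' seen so far are checkpointed each epoch and returned at the end, and if
#' the positive-patch loss saturates (predictions collapse to empty masks)
#' the checkpoint is restored, the step size halved and the optimizer
#' moments reset before training continues.
#'
#' @param patches named list of numeric patch matrices.
#' @param masks list of binary masks parallel to `patches`.
#' @param net_config a [segNetConfig()].
#' @param train_config a [segTrainConfig()].
#' @return a trained [SegNet-class]; `object@state$history` holds the mean
#'   mined-pool loss per epoch.
#' @export
trainSegmenter <- function(patches, masks, net_config = segNetConfig(),
                           train_config = segTrainConfig()) {
  stopifnot(length(patches) == length(masks), length(patches) >= 1)
  if (is.null(names(patches)))
    names(patches) <- sprintf("patch%05d", seq_along(patches))
  names(masks) <- names(patches)
  ord <- order(names(patches))
  patches <- patches[ord]; masks <- masks[ord]
  xs <- lapply(patches, .prepPatch, config = net_config)
  ys <- lapply(masks, .cropMask, config = net_config)
  is_pos <- vapply(ys, function(m) sum(m) > 0, logical(1))
  if (!any(is_pos)) stop("refusing to train: no positive masks in the pool")
  net <- buildSegNet(net_config, seed = substreamSeed(train_config$seed, "init"))
  p <- net@params
  adam <- list(m = rapply(p, function(x) x * 0, how = "replace"),
               v = rapply(p, function(x) x * 0, how = "replace"), t = 0L)
  lr <- train_config$learning_rate
  b1 <- train_config$beta1; b2 <- 0.999; ee <- 1e-8
  al <- train_config$tversky_alpha; be <- train_config$tversky_beta
  netl <- list(config = net@config, params = p)
  history <- numeric(train_config$epochs)
  best <- list(params = netl$params, pos_loss = Inf)
  set.seed(substreamSeed(train_config$seed, "epochs"))
  for (ep in seq_len(train_config$epochs)) {
    losses <- vapply(seq_along(xs), function(i) {
      fw <- .segFwd(netl, xs[[i]])
      tverskyLoss(fw$prob, ys[[i]], al, be)
    }, numeric(1))
    pos_loss <- mean(losses[is_pos])
    if (pos_loss < best$pos_loss)
      best <- list(params = netl$params, pos_loss = pos_loss)
    if (ep > 1L && pos_loss > 0.995 && best$pos_loss < 0.99) {
      # collapse to empty predictions: back off to the checkpoint
      netl$params <- best$params
      lr <- lr / 2
      adam <- list(m = rapply(netl$params, function(x) x * 0, how = "replace"),
                   v = rapply(netl$params, function(x) x * 0, how = "replace"),
                   t = 0L)
    }
    keep <- mineHardNegatives(losses, is_pos, train_config$hard_negative_ratio)
    history[ep] <- mean(losses[keep])
    # class-balanced minibatches: half of each batch is lesion-positive
    # (cycled when positives are scarce), so every optimization step carries
    # foreground gradient signal
    kp <- keep[is_pos[keep]]; kn <- keep[!is_pos[keep]]
    kp <- kp[sample.int(length(kp))]; kn <- kn[sample.int(length(kn))]
    bs <- train_config$batch_size
    n_batches <- max(1L, ceiling(length(keep) / bs))
    half <- max(1L, bs %/% 2L)
    batches <- vector("list", n_batches)
    for (bi in seq_len(n_batches)) {
      pos_idx <- if (length(kp)) kp[((bi - 1L) * half + seq_len(half) - 1L) %% length(kp) + 1L] else integer(0)
      neg_idx <- if (length(kn)) kn[((bi - 1L) * half + seq_len(min(half, bs - length(pos_idx))) - 1L) %% length(kn) + 1L] else integer(0)
      batches[[bi]] <- unique(c(pos_idx, neg_idx))
    }
    for (idx in batches) {
      grads <- NULL
      for (i in idx) {
        fw <- .segFwd(netl, xs[[i]], cache = TRUE)
        dprob <- .tverskyGrad(fw$prob, ys[[i]], al, be) / length(idx)
        g <- .segBwd(netl, dprob, fw$cache)
        if (is.null(grads)) grads <- g
        else for (nm in names(g)) {
          grads[[nm]]$W <- grads[[nm]]$W + g[[nm]]$W
          grads[[nm]]$b <- grads[[nm]]$b + g[[nm]]$b
        }
      }
      adam$t <- adam$t + 1L
      corr1 <- 1 - b1^adam$t; corr2 <- 1 - b2^adam$t
      for (nm in names(grads)) {
        for (slot in c("W", "b")) {
          gv <- grads[[nm]][[slot]]
          adam$m[[nm]][[slot]] <- b1 * adam$m[[nm]][[slot]] + (1 - b1) * gv
          adam$v[[nm]][[slot]] <- b2 * adam$v[[nm]][[slot]] + (1 - b2) * gv^2
          mh <- adam$m[[nm]][[slot]] / corr1
          vh <- adam$v[[nm]][[slot]] / corr2
          netl$params[[nm]][[slot]] <- netl$params[[nm]][[slot]] - lr * mh / (sqrt(vh) + ee)
        }
      }
    }
  }
  # final evaluation: return whichever weights segment the positives best
  final_pos <- mean(vapply(which(is_pos), function(i) {
    fw <- .segFwd(netl, xs[[i]])
    tverskyLoss(fw$prob, ys[[i]], al, be)
  }, numeric(1)))
  if (best$pos_loss < final_pos) netl$params <- best$params
  new("SegNet", config = net@config, params = netl$params,
      state = list(history = history, train_config = unclass(train_config)),
      trained = TRUE,
      fingerprint = paste0(net@fingerprint, sprintf("-e%d-s%d",
                           train_config$epochs, train_config$seed)))
}

#' Predict a segmentation probability map for one patch
#'
#' @param net a [SegNet-class].
#' @param patch numeric patch matrix (centre-cropped to the input size).
#' @return matrix of per-pixel probabilities.
#' @export
predictSegNet <- function(net, patch) {
  x <- .prepPatch(patch, net@config)
  .segFwd(list(config = net@config, params = net@params), x)$prob
}

#' Global-max-pool feature head for one patch
#'
#' Runs the encoder + bottleneck only and returns the maximum activation of
#' each bottleneck map (`bottleneck_channels` values).
#'
#' @param net a [SegNet-class].
#' @param patch numeric patch matrix.
#' @return numeric feature vector.
#' @export
segFeatureHead <- function(net, patch) {
  x <- .prepPatch(patch, net@config)
  .segFwd(list(config = net@config, params = net@params), x,
          features_only = TRUE)$features
}

#' Choose the representative slice from per-slice predicted areas
#'
#' Returns the index of the slice with the largest predicted segmentation
#' area; ties break to the earliest slice. When no slice has any predicted
#' segmentation, the middle (third) candidate slice is chosen.
#'
#' @param areas numeric vector of predicted-mask areas, one per candidate
#'   slice.
#' @return integer slice index within the candidate range.
#' @export
selectRepresentativeSlice <- function(areas) {
  if (all(areas == 0)) return(3L)
  as.integer(which.max(areas))
}

#' Extract a patient's deep feature vector
#'
#' Segments all 12 patches, picks the representative slice (largest
#' predicted area, middle slice when nothing is predicted), runs the
#' feature head on that slice's two hemispheric patches, and returns the
#' per-channel elementwise maximum of the two -- so the vector is invariant
#' to which hemisphere carries the lesion.
#'
#' @param net a trained [SegNet-class].
#' @param stack an [ROIStack-class].
#' @param threshold binarization threshold defining "predicted
#'   segmentation" area.
#' @return a [DeepFeatures-class].
#' @export
extractDeepFeatures <- function(net, stack, threshold = 0.5) {
  if (!isTrained(net)) stop("network is untrained; call trainSegmenter() first")
  pts <- patches(stack)
  prov <- provenance(stack)
  slices <- unique(prov$slice)
  areas <- vapply(slices, function(s) {
    ii <- which(prov$slice == s)
    sum(vapply(ii, function(i)
      sum(predictSegNet(net, pts[[i]]) >= threshold), numeric(1)))
  }, numeric(1))
  sel <- selectRepresentativeSlice(areas)
  ii <- which(prov$slice == slices[sel])
  f <- do.call(pmax, lapply(ii, function(i) segFeatureHead(net, pts[[i]])))
  new("DeepFeatures", patientId = patientId(stack), values = f,
      sourceSlice = sel)
}
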