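#' A stack of rate layers trained layer-locally
#'
#' Dense layers; each layer optimises the LPL objective on its own inputs
#' and outputs, with no gradient flow between layers (stop-gradient). The
#' input to layer `l + 1` is the (detached) activity of layer `l`.
#'
#' @param sizes Integer vector of dimensions `c(n_in, h1, ..., n_out)`.
#' @param activation Hidden/output activation (see [rate_layer()]); default
#'   a smooth rectifier.
#' @param hyper A single [lpl_hyperparams()] applied to every layer, or a
#'   list with one per layer.
#' @param standardize Input normalisation applied before every hidden layer
#'   (the first layer always sees raw inputs), with batch statistics
#'   treated as constants: `"full"` (default) removes each unit's batch
#'   mean and divides by its batch standard deviation, the
#'   batch-normalisation analogue customary in this network family and
#'   needed for decorrelation to act evenly across units at depth;
#'   `"center"` removes only the mean; `"none"` feeds raw activities.
#' @param seed Integer seed.
#' @return An object of class `layer_stack`.
#' @export
layer_stack <- function(sizes, activation = "softplus0",
                        hyper = lpl_hyperparams(eta = 0.005, lambda2 = 50,
                                                eta_w = 0.01, epsilon = 1e-3),
                        standardize = c("full", "center", "none"),
                        seed = 1L) {
  standardize <- match.arg(standardize)
  stopifnot(length(sizes) >= 2)
  n_layers <- length(sizes) - 1L
  if (inherits(hyper, "lpl_hyperparams")) hyper <- rep(list(hyper), n_layers)
  set.seed(seed)
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers))
    layers[[l]] <- rate_layer(sizes[l], sizes[l + 1L], activation,
                              hyper = hyper[[l]])
  structure(list(layers = layers, sizes = sizes, standardize = standardize),
            class = "layer_stack")
}

standardize_cols <- function(x, center, scale) {
  sweep(sweep(x, 2, center), 2, scale, "/")
}

#' Forward pass through a layer stack
#'
#' @param stack A [layer_stack()].
#' @param x B x N input matrix.
#' @return List of per-layer activity matrices; the last entry is the
#'   output representation.
#' @export
layer_forward <- function(stack, x) {
  x <- as.matrix(x)
  if (ncol(x) != stack$sizes[1]) stop("input dimension mismatch")
  acts <- vector("list", length(stack$layers))
  h <- x
  for (l in seq_along(stack$layers)) {
    if (l > 1 && stack$standardize != "none") {
      scl <- if (stack$standardize == "full") apply(h, 2, sd) + 1e-6 else 1
      h <- standardize_cols(h, colMeans(h), scl)
    }
    h <- layer_activity(stack$layers[[l]], h)$z
    acts[[l]] <- h
  }
  acts
}

#' One layer-local training step
#'
#' Propagates both members of the pair through the stack and applies each
#' layer's closed-form LPL update to its own (input, output) pair. Because
#' layers are updated from detached inputs, the update of layer `l` never
#' depends on layers deeper than `l`.
#'
#' @param stack A [layer_stack()].
#' @param batch A [paired_batch()].
#' @param apply If `TRUE` (default) the updates are added to the weights.
#' @return List with the updated `stack` and `dW` (per-layer update list).
#' @export
layerwise_train_step <- function(stack, batch, apply = TRUE) {
  x_prev <- as.matrix(batch$x_prev)
  x_curr <- as.matrix(batch$x_curr)
  dWs <- vector("list", length(stack$layers))
  for (l in seq_along(stack$layers)) {
    layer <- stack$layers[[l]]
    if (l > 1 && stack$standardize != "none") {
      # shared (detached) batch statistics keep the two views comparable
      pooled <- rbind(x_prev, x_curr)
      ctr <- colMeans(pooled)
      scl <- if (stack$standardize == "full") apply(pooled, 2, sd) + 1e-6 else 1
      x_prev <- standardize_cols(x_prev, ctr, scl)
      x_curr <- standardize_cols(x_curr, ctr, scl)
    }
    upd <- lpl_weight_update(layer, paired_batch(x_prev, x_curr))
    dWs[[l]] <- upd$dW
    if (apply) stack$layers[[l]]$W <- layer$W + upd$dW
    # next layer sees the *pre-update* detached activities
    x_prev <- upd$z_prev
    x_curr <- upd$z_curr
  }
  list(stack = stack, dW = dWs)
}

#' Contrastive baseline loss (toy scale)
#'
#' `sum_b [ -sim(v_b, v_prev_b) + sum_{b' != b} sim(v_b, v_b') ]` with
#' cosine similarity; no gradient through `v_prev`. The within-batch terms
#' are the negative samples the LPL rule avoids.
#'
#' @param v_curr,v_prev B x D projection matrices.
#' @return Scalar loss in `[-B - B(B-1), B + B(B-1)]`.
#' @export
contrastive_loss <- function(v_curr, v_prev) {
  v_curr <- as.matrix(v_curr); v_prev <- as.matrix(v_prev)
  if (!identical(dim(v_curr), dim(v_prev))) stop("shape mismatch")
  nc <- sqrt(rowSums(v_curr^2)); np <- sqrt(rowSums(v_prev^2))
  if (any(nc == 0) || any(np == 0)) stop("zero-norm vector")
  vc <- v_curr / nc
  pos <- sum(rowSums(vc * (v_prev / np)))
  S <- vc %*% t(vc)
  neg <- sum(S) - sum(diag(S))
  -pos + neg
}

#' Train a contrastive single-layer baseline by gradient descent
#'
#' Minimal paired-view learner used as a sanity anchor: one linear layer
#' trained on [contrastive_loss()] with numerical-free analytic gradients.
#'
#' @param batches List of [paired_batch()] objects (views of the same
#'   underlying stimuli).
#' @param n_out Output dimension.
#' @param eta Learning rate.
#' @param epochs Passes over the batch list.
#' @param seed Integer seed.
#' @return Weight matrix `n_out x n_in`.
#' @export
train_contrastive_linear <- function(batches, n_out = 8L, eta = 0.01,
                                     epochs = 20L, seed = 1L) {
  set.seed(seed)
  n_in <- ncol(batches[[1]]$x_curr)
  W <- matrix(rnorm(n_out * n_in, sd = 1 / sqrt(n_in)), n_out, n_in)
  grad_num <- function(W, b) {
    # analytic gradient of the cosine-similarity loss wrt W (z = W x)
    xc <- as.matrix(b$x_curr); xp <- as.matrix(b$x_prev)
    vc <- xc %*% t(W); vp <- xp %*% t(W)
    nc <- sqrt(rowSums(vc^2)); np <- sqrt(rowSums(vp^2))
    u <- vc / nc; w <- vp / np
    B <- nrow(vc)
    S <- u %*% t(u)
    G <- matrix(0, nrow(vc), ncol(vc))
    for (b_i in seq_len(B)) {
      # d/dv_b of -sim(v_b, w_b): -(w_b - (u_b . w_b) u_b)/||v_b||
      cb <- sum(u[b_i, ] * w[b_i, ])
      g <- -(w[b_i, ] - cb * u[b_i, ]) / nc[b_i]
      # d/dv_b of sum_{b' != b} sim twice (symmetric): 2 * sum_{b'} (u_b' - S u_b)/||v_b||
      others <- colSums(u) - u[b_i, ]
      sums <- sum(S[b_i, ]) - 1
      g <- g + 2 * (others - sums * u[b_i, ]) / nc[b_i]
      G[b_i, ] <- g
    }
    t(G) %*% xc
  }
  for (ep in seq_len(epochs))
    for (b in batches)
      W <- W - eta * grad_num(W, b)
  W
}

#' Train a layer stack on a paired-view stream
#'
#' Ablations: `full` (all three terms), `pred_off` (no predictive term),
#' `hebb_off` (no Hebbian term), `decorr_off` (no decorrelation term) and
#' `shuffled` (full rule, but the pairing between views is permuted so
#' temporal contingency is destroyed).
#'
#' @param stack A [layer_stack()].
#' @param stream A function `(i)` returning the `i`-th [paired_batch()], or
#'   a list of batches.
#' @param n_steps Number of training steps.
#' @param ablation Ablation name.
#' @param seed Integer seed (used for the shuffled pairing).
#' @return List with the trained `stack` and `diagnostics` (per-layer mean
#'   activity over the last batch).
#' @export
train_network <- function(stack, stream, n_steps = length(stream),
                          ablation = c("full", "pred_off", "hebb_off",
                                       "decorr_off", "shuffled"),
                          seed = 1L) {
  ablation <- match.arg(ablation)
  set.seed(seed)
  get_batch <- if (is.function(stream)) stream else function(i)
    stream[[(i - 1L) %% length(stream) + 1L]]
  for (l in seq_along(stack$layers)) {
    h <- stack$layers[[l]]$hyper
    if (ablation == "hebb_off") h$lambda1 <- 0
    if (ablation == "decorr_off") h$lambda2 <- 0
    stack$layers[[l]]$hyper <- h
  }
  last <- NULL
  for (i in seq_len(n_steps)) {
    batch <- get_batch(i)
    if (ablation == "shuffled") {
      perm <- sample.int(nrow(batch$x_prev))
      batch <- paired_batch(batch$x_prev[perm, , drop = FALSE], batch$x_curr)
    }
    if (ablation == "pred_off") {
      # drop the predictive term by presenting the current view as its own past
      batch <- paired_batch(batch$x_curr, batch$x_curr)
    }
    res <- layerwise_train_step(stack, batch)
    stack <- res$stack
    last <- batch
  }
  acts <- layer_forward(stack, last$x_curr)
  diag <- data.frame(layer = seq_along(acts),
                     mean_activity = vapply(acts, function(z) mean(abs(z)),
                                            numeric(1)))
  list(stack = stack, diagnostics = diag)
}

#' Paired-batch stream from a latent-factor video
#'
#' Consecutive frames within a clip become (previous, current) pairs;
#' cross-clip transitions are included, mirroring the occasional object
#' switches of a continuous video.
#'
#' @param video Output of [gen_latent_video()].
#' @param batch_size Pairs per batch.
#' @param gain_sd,offset_sd Optional per-view contrast and brightness
#'   jitter: each view is scaled by `1 + N(0, gain_sd)` and shifted by
#'   `N(0, offset_sd)` (defaults 0, i.e. raw consecutive frames). These
#'   play the role of the colour/contrast jitter of paired-view pipelines;
#'   at desk scale they suppress overall feature variance and reduce
#'   representation dimensionality, so they are off by default (see the
#'   methods vignette).
#' @param noise_sd Standard deviation of additional independent pixel noise
#'   (default 0).
#' @return A function `(i)` returning a [paired_batch()] with a `labels`
#'   attribute (current-frame rows of the video's label table).
#' @export
video_stream <- function(video, batch_size = 64L, gain_sd = 0,
                         offset_sd = 0, noise_sd = 0) {
  n <- dim(video$frames)[3]
  flat <- matrix(video$frames, ncol = n)
  force(batch_size); force(gain_sd); force(offset_sd); force(noise_sd)
  jitter_view <- function(x) {
    if (gain_sd > 0) x <- x * (1 + rnorm(nrow(x), 0, gain_sd))
    if (offset_sd > 0) x <- x + rnorm(nrow(x), 0, offset_sd)
    if (noise_sd > 0) x <- x + matrix(rnorm(length(x), 0, noise_sd), nrow(x))
    x
  }
  function(i) {
    idx <- sample.int(n - 1L, batch_size, replace = TRUE)
    xp <- jitter_view(t(flat[, idx, drop = FALSE]))
    xc <- jitter_view(t(flat[, idx + 1L, drop = FALSE]))
    b <- paired_batch(xp, xc)
    attr(b, "labels") <- video$labels[idx + 1L, , drop = FALSE]
    b
  }
}
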