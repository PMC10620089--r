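#' Hyperparameters of the rate-based LPL rule
#'
#' @param eta Learning rate (> 0).
#' @param lambda1 Strength of the Hebbian (variance) term; fixed at 1 in all
#'   reference simulations.
#' @param lambda2 Strength of the decorrelation term.
#' @param eta_w Weight-decay coefficient.
#' @param epsilon Variance floor added inside `log(sigma^2 + epsilon)` for
#'   numerical stability (default 1e-6).
#' @param delta_t Prediction horizon in discrete steps (default 1; the
#'   temporal derivative of the activity is approximated by
#'   `z(t) - z(t - delta_t)` with all constants absorbed into `eta`).
#' @return An object of class `lpl_hyperparams`.
#' @export
lpl_hyperparams <- function(eta = 0.01, lambda1 = 1, lambda2 = 1,
                            eta_w = 0, epsilon = 1e-6, delta_t = 1L) {
  stopifnot(eta > 0, epsilon > 0, lambda1 >= 0, lambda2 >= 0, eta_w >= 0)
  structure(list(eta = eta, lambda1 = lambda1, lambda2 = lambda2,
                 eta_w = eta_w, epsilon = epsilon,
                 delta_t = as.integer(delta_t)),
            class = "lpl_hyperparams")
}

activation_fns <- function(name) {
  switch(name,
    linear = list(f = identity, fprime = function(a) rep(1, length(a))),
    softplus = list(
      f = function(a) ifelse(a > 30, a, log1p(exp(pmin(a, 30)))),
      fprime = function(a) 1 / (1 + exp(-a))),
    softplus0 = list( # shifted so f(0) = 0: zero weights give zero activity
      f = function(a) ifelse(a > 30, a, log1p(exp(pmin(a, 30)))) - log(2),
      fprime = function(a) 1 / (1 + exp(-a))),
    tanh_pos = list( # smooth rectifier saturating at 2
      f = function(a) 1 + tanh(a),
      fprime = function(a) 1 / cosh(a)^2),
    stop("unknown activation: ", name))
}

#' A rate layer with plastic weights and running output moments
#'
#' Holds the weight matrix `W` (M x N), a monotone activation with available
#' derivative, per-output running mean/variance estimates and the rule's
#' hyperparameters. Weights are initialised zero-mean Gaussian with standard
#' deviation `1/sqrt(n_in)` (scale-free start).
#'
#' @param n_in,n_out Input and output dimensions.
#' @param activation One of `"linear"`, `"softplus"`, `"tanh_pos"`.
#' @param hyper An [lpl_hyperparams()].
#' @param moment_mode One of `"batch"` (moments from the current batch),
#'   `"stale"` (previous batch) or `"exponential"` (leaky averages).
#' @param moment_tau Time constant (in batches) for the exponential mode.
#' @param seed Integer seed or `NULL`.
#' @return An object of class `rate_layer`.
#' @export
rate_layer <- function(n_in, n_out = 1L, activation = "linear",
                       hyper = lpl_hyperparams(),
                       moment_mode = c("batch", "stale", "exponential"),
                       moment_tau = 50, seed = NULL) {
  moment_mode <- match.arg(moment_mode)
  if (!is.null(seed)) set.seed(seed)
  act <- activation_fns(activation)
  structure(list(
    W = matrix(rnorm(n_out * n_in, sd = 1 / sqrt(n_in)), n_out, n_in),
    activation = activation, f = act$f, fprime = act$fprime,
    hyper = hyper, moment_mode = moment_mode, moment_tau = moment_tau,
    zbar = rep(0, n_out), sigma2 = rep(1, n_out), moments_ready = FALSE),
    class = "rate_layer")
}

layer_activity <- function(layer, x) {
  a <- x %*% t(layer$W)
  list(a = a, z = layer$f(a))
}

#' Predictive loss: mean squared consecutive activity difference
#'
#' `(1 / (2 M B)) * sum_b ||z_curr^b - z_prev^b||^2`, with no gradient
#' through `z_prev` (the past is a fixed target).
#'
#' @param z_curr,z_prev B x M activity matrices at `t` and `t - dt`.
#' @return Nonnegative scalar.
#' @export
predictive_loss <- function(z_curr, z_prev) {
  z_curr <- as.matrix(z_curr); z_prev <- as.matrix(z_prev)
  if (!identical(dim(z_curr), dim(z_prev))) stop("shape mismatch")
  sum((z_curr - z_prev)^2) / (2 * ncol(z_curr) * nrow(z_curr))
}

#' Hebbian loss: negative log variance of activity
#'
#' `(1 / M) * sum_i -log(sigma_i^2 + epsilon)` with the `B - 1`-normalised
#' sample variance per output neuron; the batch mean is treated as constant
#' for gradients.
#'
#' @param z_curr B x M activity matrix, B >= 2.
#' @param epsilon Variance floor.
#' @return Scalar (negative when variances exceed 1).
#' @export
hebbian_loss <- function(z_curr, epsilon = 0) {
  z_curr <- as.matrix(z_curr)
  if (nrow(z_curr) < 2) stop("batch size must be at least 2")
  s2 <- apply(z_curr, 2, var)
  mean(-log(s2 + epsilon))
}

#' Decorrelation loss
#'
#' As printed: `1/((B-1)(M^2-M)) * sum_b sum_i sum_{k != i}
#' (z_i^b - zbar_i)^2 (z_k^b - zbar_k)^2` over ordered pairs `k != i`
#' (`variant = "printed"`, the default). The verbal description — the sum of
#' squared off-diagonal covariance entries — is available as
#' `variant = "covariance"`. Returns 0 for M = 1 by convention.
#'
#' @param z_curr B x M activity matrix.
#' @param variant `"printed"` or `"covariance"`.
#' @return Nonnegative scalar.
#' @export
decorrelation_loss <- function(z_curr, variant = c("printed", "covariance")) {
  variant <- match.arg(variant)
  z_curr <- as.matrix(z_curr)
  M <- ncol(z_curr); B <- nrow(z_curr)
  if (M < 2) return(0)
  d <- sweep(z_curr, 2, colMeans(z_curr))
  if (variant == "printed") {
    d2 <- d^2
    rows <- rowSums(d2)
    # sum_i sum_{k != i} d_i^2 d_k^2 = (sum d^2)^2 - sum d^4, per sample
    tot <- sum(rows^2) - sum(d2^2)
    tot / ((B - 1) * (M^2 - M))
  } else {
    cv <- crossprod(d) / (B - 1)
    (sum(cv^2) - sum(diag(cv)^2)) / (M^2 - M)
  }
}

#' Full rate-based LPL objective
#'
#' `L_pred + lambda1 * L_Hebb + lambda2 * L_decorr` plus L2 weight decay.
#' Used by the numerical-gradient oracle in the tests.
#'
#' @param layer A [rate_layer()].
#' @param batch A [paired_batch()].
#' @param zbar Optional fixed mean estimate (stop-gradient); default: batch
#'   mean of the current activity. The variance is always recomputed from
#'   the activity around `zbar`, since the gradient flows through it.
#' @param z_prev Optional fixed previous-step activity (stop-gradient);
#'   default: forward pass on `batch$x_prev` through the current weights.
#'   Pass the unperturbed activities when using this as a
#'   numerical-gradient oracle.
#' @return Scalar loss.
#' @export
lpl_loss <- function(layer, batch, zbar = NULL, z_prev = NULL) {
  h <- layer$hyper
  zc <- layer_activity(layer, batch$x_curr)$z
  zp <- if (is.null(z_prev)) layer_activity(layer, batch$x_prev)$z else z_prev
  M <- ncol(zc); B <- nrow(zc)
  if (is.null(zbar)) zbar <- colMeans(zc)
  d <- sweep(zc, 2, zbar)
  sigma2 <- colSums(d^2) / (B - 1)
  l_pred <- sum((zc - zp)^2) / (2 * M * B)
  l_hebb <- mean(-log(sigma2 + h$epsilon))
  l_dec <- if (M >= 2) {
    d2 <- d^2
    (sum(rowSums(d2)^2) - sum(d2^2)) / ((B - 1) * (M^2 - M))
  } else 0
  l_pred + h$lambda1 * l_hebb + h$lambda2 * l_dec +
    h$eta_w * sum(layer$W^2) / 2
}

#' Closed-form LPL weight update for one layer
#'
#' Returns `-eta * grad_W(L_pred + lambda1 L_Hebb + lambda2 L_decorr)
#' - eta * eta_w * W` under the stop-gradient conventions: no gradient flows
#' through the previous activity, the mean estimate or the variance
#' estimate. Moments come from the layer state as set by [update_moments()]
#' (batch mode recomputes them from the current activity).
#'
#' @param layer A [rate_layer()].
#' @param batch A [paired_batch()].
#' @param moments Optional list with `zbar` and `sigma2` overriding the
#'   layer's state.
#' @return A list with `dW` (M x N), the activities `z_curr`, `z_prev`, and
#'   the moments used.
#' @export
lpl_weight_update <- function(layer, batch, moments = NULL) {
  h <- layer$hyper
  cur <- layer_activity(layer, batch$x_curr)
  prev <- layer_activity(layer, batch$x_prev)
  zc <- cur$z; zp <- prev$z
  M <- ncol(zc); B <- nrow(zc)
  if (is.null(moments)) {
    if (layer$moment_mode == "batch") {
      if (B < 2) stop("batch moments require B >= 2")
      moments <- list(zbar = colMeans(zc), sigma2 = apply(zc, 2, var))
    } else {
      if (!layer$moments_ready)
        stop("stale/exponential moments requested before any update_moments() call")
      moments <- list(zbar = layer$zbar, sigma2 = layer$sigma2)
    }
  }
  zbar <- moments$zbar; sigma2 <- moments$sigma2
  d <- sweep(zc, 2, zbar)

  # per-(sample, neuron) error factors; see the loss definitions
  g_pred <- (zc - zp) / (M * B)
  g_hebb <- if (h$lambda1 == 0 || B < 2) {
    if (h$lambda1 > 0) stop("batch moments require B >= 2")
    matrix(0, B, M)
  } else {
    sweep(d, 2, -2 / ((B - 1) * M * (sigma2 + h$epsilon)), `*`)
  }
  if (M >= 2) {
    d2 <- d^2
    g_dec <- 4 * d * (rowSums(d2) - d2) / ((B - 1) * (M^2 - M))
  } else {
    g_dec <- matrix(0, B, M)
  }
  err <- (g_pred + h$lambda1 * g_hebb + h$lambda2 * g_dec) * layer$fprime(cur$a)
  dW <- -h$eta * (t(err) %*% batch$x_curr) - h$eta * h$eta_w * layer$W
  list(dW = dW, z_curr = zc, z_prev = zp, moments = moments)
}

#' Update a layer's running output moments
#'
#' Mode `batch`: moments of the supplied activity; `stale`: the moments
#' stored from the previous call become current while the new batch moments
#' are staged; `exponential`: leaky averages with time constant
#' `layer$moment_tau` batches.
#'
#' @param layer A [rate_layer()].
#' @param z_curr B x M activity matrix.
#' @return The layer with `zbar`, `sigma2` updated.
#' @export
update_moments <- function(layer, z_curr) {
  z_curr <- as.matrix(z_curr)
  m <- colMeans(z_curr)
  s2 <- if (nrow(z_curr) >= 2) apply(z_curr, 2, var) else rep(0, ncol(z_curr))
  switch(layer$moment_mode,
    batch = { layer$zbar <- m; layer$sigma2 <- s2 },
    stale = {
      if (layer$moments_ready) {
        layer$zbar <- layer$staged_zbar
        layer$sigma2 <- layer$staged_sigma2
      } else {
        layer$zbar <- m; layer$sigma2 <- s2
      }
      layer$staged_zbar <- m; layer$staged_sigma2 <- s2
    },
    exponential = {
      k <- 1 / layer$moment_tau
      if (!layer$moments_ready) {
        layer$zbar <- m; layer$sigma2 <- s2
      } else {
        layer$zbar <- layer$zbar + k * (m - layer$zbar)
        layer$sigma2 <- layer$sigma2 + k * (s2 - layer$sigma2)
      }
    },
    stop("unknown moment mode"))
  layer$moments_ready <- TRUE
  layer
}

#' BCM-style sliding threshold of the LPL rule
#'
#' `Theta = zbar + (sigma2 / lambda) * dz_dt`. Writing the update as
#' `eta * lambda * x f'(a) / sigma2 * (z - Theta)` reproduces the direct
#' form `eta * x f'(a) * (-dz_dt + lambda / sigma2 * (z - zbar))`
#' identically.
#'
#' @param zbar Running mean activity.
#' @param sigma2 Running activity variance.
#' @param lambda Hebbian strength (> 0).
#' @param dz_dt Rate of change of the postsynaptic activity.
#' @return The sliding threshold.
#' @export
sliding_threshold <- function(zbar, sigma2, lambda, dz_dt) {
  if (any(lambda == 0)) stop("'lambda' must be nonzero")
  zbar + sigma2 / lambda * dz_dt
}

#' Single-synapse LPL update, direct and sliding-threshold forms
#'
#' Continuous-time single-neuron forms used to verify the algebraic identity
#' between the two formulations.
#'
#' @param x Presynaptic activity vector.
#' @param z,zbar,sigma2,dz_dt Postsynaptic activity, running mean, running
#'   variance, rate of change.
#' @param fprime_a Activation derivative at the operating point.
#' @param eta,lambda Learning rate and Hebbian strength.
#' @param form `"direct"` (predictive + Hebbian sum) or `"threshold"`
#'   (BCM-style with [sliding_threshold()]).
#' @return Weight derivative vector `dW/dt`.
#' @export
lpl_update_single <- function(x, z, zbar, sigma2, dz_dt, fprime_a = 1,
                              eta = 1e-3, lambda = 1,
                              form = c("direct", "threshold")) {
  form <- match.arg(form)
  if (form == "direct") {
    eta * x * fprime_a * (-dz_dt + lambda / sigma2 * (z - zbar))
  } else {
    theta <- sliding_threshold(zbar, sigma2, lambda, dz_dt)
    eta * lambda * x * fprime_a / sigma2 * (z - theta)
  }
}

#' Oja's rule update
#'
#' `dw = eta * z * (x - z * w)` with `z = w . x`; converges to the leading
#' principal component of the input with unit norm.
#'
#' @param w Weight vector.
#' @param x Input vector (or B x N matrix for a batch-averaged update).
#' @param eta Learning rate.
#' @return Weight increment of the same shape as `w`.
#' @export
oja_update <- function(w, x, eta = 0.01) {
  if (is.matrix(x)) {
    z <- as.numeric(x %*% w)
    eta * colMeans(z * (x - outer(z, w)))
  } else {
    z <- sum(w * x)
    eta * z * (x - z * w)
  }
}

#' Train a single linear neuron on the two-cluster task
#'
#' Repeatedly draws paired batches from the 2D cluster sequence and applies
#' the selected learning rule. Rules: `lpl` (full single-neuron rule),
#' `pred_off` (Hebbian-only), `hebb_off` (predictive-only),
#' `no_var_modulation` (LPL with the variance estimate replaced by 1) and
#' `oja`.
#'
#' @param config A [cluster_sequence_config()] describing the data stream;
#'   its `n_pairs` is the batch size.
#' @param rule Learning rule name.
#' @param epochs Number of batch updates.
#' @param hyper An [lpl_hyperparams()].
#' @param seed Integer seed.
#' @param probe_n Probe-set size for the final selectivity measurement.
#' @param record_every Store trajectory rows every this many epochs.
#' @return List with `weights` (final), `trajectory` (data frame: epoch,
#'   w_x, w_y, mean_activity, var_activity), `selectivity` (final cluster
#'   selectivity, see [cluster_selectivity()]) and `initial_activity`.
#' @export
train_single_neuron <- function(config, rule = c("lpl", "pred_off", "hebb_off",
                                                 "no_var_modulation", "oja"),
                                epochs = 300L, hyper = lpl_hyperparams(eta = 0.05),
                                seed = 1L, probe_n = 2000L, record_every = 10L) {
  rule <- match.arg(rule)
  set.seed(seed)
  w <- rnorm(2, sd = 1 / sqrt(2))
  h <- hyper
  traj <- list()
  cfg <- config; cfg$seed <- NULL
  mean_z0 <- NULL
  for (ep in seq_len(epochs)) {
    batch <- gen_cluster_pairs(cfg)
    xc <- batch$x_curr; xp <- batch$x_prev
    zc <- as.numeric(xc %*% w); zp <- as.numeric(xp %*% w)
    B <- length(zc)
    zbar <- mean(zc)
    s2 <- var(zc)
    if (is.null(mean_z0)) mean_z0 <- mean(abs(zc))
    dw <- switch(rule,
      oja = oja_update(w, xc, h$eta),
      {
        g_pred <- if (rule == "hebb_off" || rule == "lpl" || rule == "no_var_modulation")
          (zc - zp) / B else 0
        if (rule == "hebb_off") {
          g_hebb <- 0
        } else {
          denom <- if (rule == "no_var_modulation") 1 else s2 + h$epsilon
          g_hebb <- -2 * h$lambda1 * (zc - zbar) / ((B - 1) * denom)
        }
        err <- g_pred + g_hebb
        -h$eta * as.numeric(t(xc) %*% err) - h$eta * h$eta_w * w
      })
    w <- w + dw
    if (ep %% record_every == 0 || ep == epochs)
      traj[[length(traj) + 1L]] <- data.frame(
        epoch = ep, w_x = w[1], w_y = w[2],
        mean_activity = mean(abs(zc)), var_activity = s2)
  }
  probe_cfg <- cluster_sequence_config(config$sigma_x, config$sigma_y,
                                       config$centers, 0, probe_n)
  probe <- gen_cluster_pairs(probe_cfg)
  z <- as.numeric(probe$x_curr %*% w)
  z1 <- mean(z[probe$cluster_curr == 2L]) # cluster at +1
  z2 <- mean(z[probe$cluster_curr == 1L]) # cluster at -1
  chi <- cluster_selectivity(z1, z2, max(z), min(z))
  list(weights = w, trajectory = do.call(rbind, traj), selectivity = chi,
       initial_activity = mean_z0, rule = rule)
}

#' Sweep the y-noise level and measure cluster selectivity per rule
#'
#' @param sigma_y_grid Grid of y standard deviations.
#' @param rules Character vector of rule names (see [train_single_neuron()]).
#' @param n_seeds Seeds per grid point.
#' @param epochs,batch_size,hyper Passed to the trainer. The default hyper
#'   includes weight decay (present in the stated single-neuron objective):
#'   it bounds the weight norm, without which the scale-free Hebbian rules
#'   stop converging in angle near the variance-degenerate point and the
#'   measured crossover smears downward.
#' @param seed_base Offset added to the per-run seeds (for reproducible
#'   derivation from one global seed).
#' @return Data frame with columns `sigma_y`, `rule`, `seed`, `selectivity`.
#' @export
selectivity_sweep <- function(sigma_y_grid, rules = c("lpl", "pred_off", "oja"),
                              n_seeds = 10L, epochs = 300L, batch_size = 256L,
                              hyper = lpl_hyperparams(eta = 0.05, eta_w = 0.2),
                              seed_base = 0L) {
  out <- list()
  for (sy in sigma_y_grid)
    for (rule in rules)
      for (s in seq_len(n_seeds)) {
        cfg <- cluster_sequence_config(sigma_y = sy, n_pairs = batch_size)
        fit <- train_single_neuron(cfg, rule, epochs = epochs, hyper = hyper,
                                   seed = seed_base + s)
        out[[length(out) + 1L]] <- data.frame(
          sigma_y = sy, rule = rule, seed = seed_base + s,
          selectivity = fit$selectivity)
      }
  do.call(rbind, out)
}

#' Locate the selectivity crossover of a sweep
#'
#' Finds the `sigma_y` at which the seed-averaged selectivity of a rule
#' first drops below `threshold`, linearly interpolating between grid
#' points.
#'
#' @param sweep Output of [selectivity_sweep()].
#' @param rule Rule name to analyse.
#' @param threshold Selectivity threshold (default 0.5).
#' @return The interpolated crossover `sigma_y` (NA if never crossed).
#' @export
selectivity_crossover <- function(sweep, rule = "oja", threshold = 0.5) {
  sub <- sweep[sweep$rule == rule, ]
  agg <- aggregate(selectivity ~ sigma_y, sub, mean)
  agg <- agg[order(agg$sigma_y), ]
  below <- which(agg$selectivity < threshold)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  if (i == 1) return(agg$sigma_y[1])
  x0 <- agg$sigma_y[i - 1]; x1 <- agg$sigma_y[i]
  y0 <- agg$selectivity[i - 1]; y1 <- agg$selectivity[i]
  x0 + (threshold - y0) * (x1 - x0) / (y1 - y0)
}

#' @importFrom stats aggregate
NULL
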