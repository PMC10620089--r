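test_that("loss components evaluate to hand-computed values", {
  # predictive: identical activity -> 0; single pair (2, 1) -> 0.5;
  # B = 2 diffs (1, -1) -> 0.5
  z <- matrix(rnorm(6), 3, 2)
  expect_identical(predictive_loss(z, z), 0)
  expect_equal(predictive_loss(matrix(2), matrix(1)), 0.5)
  expect_equal(predictive_loss(matrix(c(1, 0), 2), matrix(c(0, 1), 2)), 0.5)
  expect_error(predictive_loss(matrix(1, 2, 2), matrix(1, 2, 3)), "mismatch")

  # hebbian: unit variance -> 0; {0, 2} -> -log 2; scaling by c shifts by
  # -2 log c per neuron
  zu <- cbind(c(0.5, -0.5, 0.5, -0.5) / sd(c(0.5, -0.5, 0.5, -0.5)))
  expect_equal(hebbian_loss(zu), 0)
  expect_equal(hebbian_loss(matrix(c(0, 2), 2)), -log(2))
  z2 <- matrix(rnorm(10), 5, 2)
  expect_equal(hebbian_loss(3 * z2), hebbian_loss(z2) - 2 * log(3))
  expect_error(hebbian_loss(matrix(1, 1, 2)), "at least 2")

  # decorrelation: zero deviations -> 0; worked 2x2 example -> 2; M = 1 -> 0
  expect_identical(decorrelation_loss(matrix(1, 4, 3)), 0)
  expect_equal(decorrelation_loss(matrix(c(1, -1, -1, 1), 2, 2)), 2)
  expect_identical(decorrelation_loss(matrix(rnorm(5), 5, 1)), 0)
})

test_that("closed-form update matches the numerical gradient oracle", {
  set.seed(3)
  for (k in 1:5) {
    hy <- lpl_hyperparams(eta = 1, lambda1 = runif(1, 0, 2),
                          lambda2 = runif(1, 0, 2), eta_w = runif(1, 0, 0.5))
    layer <- rate_layer(3, 2, sample(c("linear", "softplus", "softplus0"), 1),
                        hyper = hy, seed = k)
    b <- tiny_batch(B = 4, N = 3, seed = 20 + k)
    upd <- lpl_weight_update(layer, b)
    num <- numerical_lpl_grad(layer, b)
    expect_lt(max(abs(upd$dW + num) / pmax(abs(num), 1e-8)), 1e-5)
  }
})

test_that("degenerate batches produce the pure-decay update", {
  # z_curr == z_prev and z_curr == zbar for all samples: only weight decay
  layer <- rate_layer(2, 2, "linear",
                      hyper = lpl_hyperparams(eta = 0.1, eta_w = 0.3), seed = 1)
  x <- matrix(1, 3, 2) # constant batch -> z constant
  b <- paired_batch(x, x)
  upd <- lpl_weight_update(layer, b)
  expect_equal(upd$dW, -0.1 * 0.3 * layer$W)
})

test_that("B = 1 single-neuron linear case reduces to the delta rule", {
  # lambda1 = lambda2 = eta_w = 0, M = 1, B = 1, linear f:
  # dW_j = -eta (z - z_prev) x_j
  hy <- lpl_hyperparams(eta = 0.2, lambda1 = 0, lambda2 = 0, eta_w = 0)
  layer <- rate_layer(3, 1, "linear", hyper = hy, seed = 2)
  xp <- matrix(c(1, 2, 3), 1); xc <- matrix(c(2, -1, 0), 1)
  z <- as.numeric(xc %*% t(layer$W)); zp <- as.numeric(xp %*% t(layer$W))
  upd <- lpl_weight_update(layer, paired_batch(xp, xc),
                           moments = list(zbar = 0, sigma2 = 1))
  expect_equal(as.numeric(upd$dW), -0.2 * (z - zp) * as.numeric(xc))
})

test_that("moment modes behave as specified", {
  layer <- rate_layer(2, 2, "linear", seed = 1)

  # batch mode on {0, 2}: zbar = 1, sigma2 = 2
  layer$moment_mode <- "batch"
  layer <- update_moments(layer, matrix(c(0, 2, 0, 2), 2, 2))
  expect_equal(layer$zbar, c(1, 1))
  expect_equal(layer$sigma2, c(2, 2))

  # stale mode: moments equal the previous call's batch moments
  st <- rate_layer(2, 1, "linear", moment_mode = "stale", seed = 1)
  st <- update_moments(st, matrix(c(0, 2), 2, 1))
  st <- update_moments(st, matrix(c(10, 14), 2, 1))
  expect_equal(st$zbar, 1)       # from the first batch
  expect_equal(st$sigma2, 2)
  st <- update_moments(st, matrix(c(0, 0), 2, 1))
  expect_equal(st$zbar, 12)      # from the second batch

  # constant stream: all modes converge to (constant, 0)
  for (mode in c("batch", "stale", "exponential")) {
    ly <- rate_layer(2, 1, "linear", moment_mode = mode, moment_tau = 5,
                     seed = 1)
    for (i in 1:200) ly <- update_moments(ly, matrix(3, 4, 1))
    expect_equal(ly$zbar, 3, tolerance = 1e-6)
    expect_equal(ly$sigma2, 0, tolerance = 1e-6)
  }
})

test_that("sliding-threshold form is identical to the direct form", {
  expect_equal(sliding_threshold(1, 2, 1, 0), 1)
  expect_equal(sliding_threshold(1, 2, 1, 0.5), 2)
  expect_error(sliding_threshold(1, 2, 0, 1), "nonzero")

  set.seed(8)
  for (k in 1:20) {
    x <- rnorm(3); z <- rnorm(1); zb <- rnorm(1)
    s2 <- runif(1, 0.1, 3); dz <- rnorm(1); lam <- runif(1, 0.2, 3)
    d1 <- lpl_update_single(x, z, zb, s2, dz, lambda = lam, form = "direct")
    d2 <- lpl_update_single(x, z, zb, s2, dz, lambda = lam, form = "threshold")
    expect_equal(d1, d2, tolerance = 1e-12)
  }
})

test_that("oja's rule finds the leading principal component", {
  # fixed point at the unit-norm leading eigenvector
  set.seed(4)
  S <- matrix(c(3, 1, 1, 1), 2, 2)
  X <- matrix(rnorm(4e4), 2e4, 2) %*% chol(S)
  ev <- eigen(cov(X))$vectors[, 1]
  expect_lt(sqrt(sum(oja_update(ev, X, eta = 1)^2)), 0.02)

  w <- rnorm(2)
  for (i in 1:400) w <- w + oja_update(w, X[sample.int(2e4, 100), ], 0.05)
  expect_equal(sqrt(sum(w^2)), 1, tolerance = 0.05)
  expect_gt(abs(sum(w * ev)), 0.99)
})

test_that("collapse dichotomy: predictive-only collapses, Hebbian-only does not", {
  # crossover pairs make every direction eventually unpredictable, so the
  # predictive-only rule collapses fully at desk scale
  cfg <- cluster_sequence_config(sigma_y = 1, crossover_prob = 0.3,
                                 n_pairs = 256)
  off <- train_single_neuron(cfg, "hebb_off", epochs = 1000, seed = 1)
  on <- train_single_neuron(cfg, "pred_off", epochs = 400, seed = 1)
  v0 <- off$trajectory$var_activity[1]
  expect_lt(tail(off$trajectory$var_activity, 1), 1e-4 * max(v0, 1))
  expect_gt(tail(on$trajectory$var_activity, 1), 0.1)
})

test_that("selectivity crossover: Hebbian rules switch at sigma_y = 1, LPL does not", {
  sel <- function(rule, sy, s) train_single_neuron(
    cluster_sequence_config(sigma_y = sy, n_pairs = 256), rule,
    epochs = 250, seed = s)$selectivity
  for (rule in c("oja", "pred_off")) {
    lo <- mean(vapply(1:3, function(s) sel(rule, 0.6, s), numeric(1)))
    hi <- mean(vapply(1:3, function(s) sel(rule, 1.6, s), numeric(1)))
    expect_gt(lo, 0.6)
    expect_lt(hi, 0.3)
  }
  lpl2 <- mean(vapply(1:3, function(s) sel("lpl", 2, s), numeric(1)))
  expect_gt(lpl2, 0.5)
})

test_that("without variance modulation activity degenerates for some lambda1", {
  # bounded non-degenerate activity fails for at least one lambda1
  degenerate <- vapply(c(0.1, 1, 10), function(l1) {
    fit <- train_single_neuron(
      cluster_sequence_config(sigma_y = 1, n_pairs = 128), "no_var_modulation",
      epochs = 300, hyper = lpl_hyperparams(eta = 0.05, lambda1 = l1),
      seed = 2)
    v <- tail(fit$trajectory$var_activity, 1)
    !is.finite(v) || v < 1e-6 || v > 1e6
  }, logical(1))
  expect_true(any(degenerate))
})

test_that("eta = 0 leaves weights unchanged and unknown rules error", {
  expect_error(lpl_hyperparams(eta = 0))
  cfg <- cluster_sequence_config(sigma_y = 1, n_pairs = 64)
  expect_error(train_single_neuron(cfg, "nonsense"), "arg")
  hy <- lpl_hyperparams(eta = 1e-12)
  fit <- train_single_neuron(cfg, "lpl", epochs = 10, hyper = hy, seed = 3)
  set.seed(3)
  w0 <- rnorm(2, sd = 1 / sqrt(2))
  expect_equal(fit$weights, w0, tolerance = 1e-6)
})
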