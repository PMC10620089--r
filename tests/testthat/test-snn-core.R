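test_that("build_network produces the declared sizes and constraints", {
  topo <- network_topology()
  net <- build_network(topo, seed = 1)
  expect_equal(net$n_in, 500L)
  expect_equal(net$n_exc, 100L)
  expect_equal(net$n_inh, 25L)
  expect_equal(dim(net$w_in_e), c(100L, 500L))
  # nonnegative weights everywhere; no inhibitory self-connections
  for (w in net[c("w_in_e", "w_in_i", "w_e_i", "w_i_e", "w_i_i")])
    expect_true(all(w >= 0))
  expect_true(all(diag(net$w_i_i) == 0))
  expect_error(network_topology(p_in_e = 1.5), "probabilities")
})

test_that("E->I connectivity follows the Gaussian profile", {
  # profile-fitting oracle: empirical connection frequency vs the profile
  topo <- network_topology(n_input = 10L, n_exc = 100L, n_inh = 25L)
  hits <- matrix(0, 25, 100)
  n_draws <- 40
  for (s in seq_len(n_draws))
    hits <- hits + build_network(topo, seed = s)$w_e_i / topo$w_e_i
  phat <- hits / n_draws
  pexp <- outer(1:25, 1:100, function(i, j) ei_profile(j, i))
  # binomial error bound at ~3 sigma on pooled cells with p not tiny
  big <- pexp > 0.2
  se <- sqrt(pexp * (1 - pexp) / n_draws)
  expect_true(all(abs(phat[big] - pexp[big]) < pmax(4 * se[big], 0.02)))
  expect_true(all(pexp <= 1))
})

test_that("membrane relaxes to leak with tau_mem (closed-form oracle)", {
  net <- single_neuron_net(w = 0.5)
  ras <- spike_raster(0.005, 1L, duration = 0.4,
                      population_slices = list(P0 = c(1L, 1L)))
  lifp <- lif_params(tau_nmda = 5, tau_ampa = 2) # fast synapses isolate tau_mem
  res <- run_snn(net, ras, 0.4, lif = lifp, lpl = quiet_lpl(),
                 istdp = quiet_istdp(), record = 1L)
  U <- res$rec_U[, 1]
  idx <- 1000:2000 # 100-200 ms: conductances have fully decayed
  dev <- U[idx] + 70
  tau_fit <- -1e-4 / mean(diff(log(dev)))
  expect_lt(abs(tau_fit / 0.020 - 1), 0.01)
})

test_that("spikes jump the threshold by delta_theta and are delayed 0.8 ms", {
  net <- single_neuron_net(w = 20)
  ras <- spike_raster(0.005, 1L, duration = 0.1,
                      population_slices = list(P0 = c(1L, 1L)))
  res <- run_snn(net, ras, 0.1, lpl = quiet_lpl(), istdp = quiet_istdp(),
                 record = 1L)
  expect_gt(length(res$raster$time), 0)
  expect_equal(max(diff(res$rec_theta[, 1])), 100, tolerance = 1e-6)

  # conductance first moves exactly 8 steps (0.8 ms) after the input spike
  g <- res$rec_gexc[, 1]
  first <- which(g > 0)[1]
  expect_equal(first, 50 + 8 + 1) # spike lands in step 50 (0-based), 1-based row
})

test_that("double-exponential filter matches the analytic impulse response", {
  dt <- 1e-4
  x <- numeric(2000); x[1] <- 1 / dt # unit-area impulse
  out <- double_exp_filter(x, 0.002, 0.010, dt)
  tt <- seq_along(out) * dt # forward-Euler output lags the input by one step
  analytic <- (exp(-tt / 0.010) - exp(-tt / 0.002)) / (0.010 - 0.002)
  expect_lt(max(abs(out - analytic)), 0.05 * max(analytic))

  # linearity and zero input
  expect_equal(double_exp_filter(numeric(100), 0.002, 0.01, dt),
               numeric(100))
  a <- rnorm(500); b <- rnorm(500)
  expect_equal(double_exp_filter(a + b, 0.002, 0.01, dt),
               double_exp_filter(a, 0.002, 0.01, dt) +
                 double_exp_filter(b, 0.002, 0.01, dt),
               tolerance = 1e-12)
})

test_that("simulation is deterministic and conserves basic sanity", {
  set.seed(3)
  inputs <- make_snn_inputs(10L, 5, seed = 3)
  topo <- network_topology(n_input = 50L, n_exc = 10L, n_inh = 3L)
  net <- build_network(topo, seed = 4)
  r1 <- run_snn(net, inputs$raster, 5, lpl = spiking_lpl_params(eta = 0.05),
                istdp = inh_stdp_params(), record = 1L)
  r2 <- run_snn(net, inputs$raster, 5, lpl = spiking_lpl_params(eta = 0.05),
                istdp = inh_stdp_params(), record = 1L)
  expect_identical(r1$raster$time, r2$raster$time)
  expect_identical(r1$w_in_e, r2$w_in_e)

  # weights stay within bounds; conductance-based membrane stays bracketed
  expect_true(all(r1$w_in_e >= 0 & r1$w_in_e <= 1))
  expect_true(all(r1$w_i_e >= 0))
  expect_true(all(r1$rec_U[, 1] > -81 & r1$rec_U[, 1] < 1))
})

test_that("halving dt changes binned population rates by a small margin", {
  set.seed(5)
  inputs <- make_snn_inputs(10L, 4, seed = 5)
  topo <- network_topology(n_input = 50L, n_exc = 10L, n_inh = 3L)
  net <- build_network(topo, seed = 6)
  rates <- vapply(c(1e-4, 5e-5), function(dt) {
    res <- run_snn(net, inputs$raster, 4, lif = lif_params(dt = dt * 1e3),
                   lpl = quiet_lpl(), istdp = quiet_istdp())
    res$exc_rate
  }, numeric(1))
  expect_lt(abs(rates[1] - rates[2]) / max(mean(rates), 1), 0.05)
})

test_that("inhibitory STDP pushes a driven neuron toward the target rate", {
  # feedforward motif: strongly driven E cell, one plastic I afferent driven
  # at a fixed rate; postsynaptic rate approaches kappa = 10 Hz
  set.seed(7)
  topo <- network_topology(n_input = 60L, n_exc = 1L, n_inh = 1L,
                           p_in_e = 1, p_in_i = 1, p_i_e = 1, p_i_i = 0,
                           w_in_e = 0.35, w_in_i = 0.3, w_e_i = 0)
  net <- build_network(topo, seed = 7)
  const5 <- structure(rep(5, 100), dt = 0.01)
  ras <- gen_poisson_raster(list(const5), 60L, duration = 120)
  res <- run_snn(net, ras, 120, lpl = quiet_lpl(),
                 istdp = inh_stdp_params())
  late <- res$raster$time > 80 & res$raster$id == 1L
  rate <- sum(late) / 40
  expect_lt(abs(rate - 10) / 10, 0.2)

  # no spikes -> no change
  net0 <- build_network(topo, seed = 7)
  empty <- spike_raster(numeric(0), integer(0), duration = 0.5)
  res0 <- run_snn(net0, empty, 0.5, lpl = quiet_lpl(),
                  istdp = inh_stdp_params())
  expect_identical(res0$w_i_e, net0$w_i_e)
})

test_that("single pre-post pair updates match explicit trace integration", {
  # one I neuron firing at t = 0.1, one E neuron forced to fire ~5 ms later
  # via strong input drive; oracle: iSTDP update from hand-integrated traces
  topo <- network_topology(n_input = 1L, n_exc = 1L, n_inh = 1L,
                           p_in_e = 1, p_in_i = 0, p_i_e = 1, p_i_i = 0,
                           w_in_e = 30, w_i_e = 0.5, w_e_i = 0)
  net <- build_network(topo, seed = 1)
  # input spike at 0.1049 (delivered 0.1057) makes E spike; I spike earlier
  # cannot be forced directly, so drive only E and check the post-spike term
  ras <- spike_raster(0.1049, 1L, duration = 0.2,
                      population_slices = list(P0 = c(1L, 1L)))
  istdp <- inh_stdp_params()
  res <- run_snn(net, ras, 0.2, lpl = quiet_lpl(), istdp = istdp)
  # I never spikes, E spikes once; the I->E weight changes only on the E
  # spike by zeta * x_i = 0 (I trace is zero) -> unchanged
  expect_equal(res$w_i_e, net$w_i_e)
})

test_that("printed literal iSTDP form is potentiation-only", {
  set.seed(9)
  inputs <- make_snn_inputs(10L, 3, seed = 9)
  topo <- network_topology(n_input = 50L, n_exc = 8L, n_inh = 3L)
  net <- build_network(topo, seed = 10)
  res <- run_snn(net, inputs$raster, 3, lpl = quiet_lpl(),
                 istdp = inh_stdp_params(literal_printed = TRUE))
  changed <- res$w_i_e[net$m_i_e == 1] - net$w_i_e[net$m_i_e == 1]
  expect_true(all(changed >= 0))
})

test_that("removing inhibition raises rates and lowers dimensionality", {
  set.seed(21)
  inputs <- make_snn_inputs(20L, 30, seed = 21)
  topo <- network_topology(n_input = 100L, n_exc = 20L, n_inh = 5L)
  net <- build_network(topo, seed = 22)
  net0 <- net
  net0$w_i_e[] <- 0 # inhibition removed
  with_i <- run_snn(net, inputs$raster, 30, lpl = quiet_lpl(),
                    istdp = inh_stdp_params())
  no_i <- run_snn(net0, inputs$raster, 30, lpl = quiet_lpl(),
                  istdp = quiet_istdp())
  expect_gt(no_i$exc_rate, with_i$exc_rate)
  pr_with <- participation_ratio(bin_raster(with_i$raster,
                                            neurons = 1:20))
  pr_without <- participation_ratio(bin_raster(no_i$raster,
                                               neurons = 1:20))
  expect_lt(pr_without, pr_with)
})
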