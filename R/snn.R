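#' Leaky integrate-and-fire neuron parameters
#'
#' Conductance-based LIF with AMPA/NMDA/GABA conductances (in units of the
#' leak conductance), a dynamic threshold implementing absolute and relative
#' refractoriness, and a fixed axonal delay. Time constants in ms, voltages
#' in mV. Reversal potentials and the NMDA/GABA/threshold time constants
#' default to standard cortical values (the source tables are not available;
#' see the methods vignette).
#'
#' @param tau_mem,tau_ampa,tau_nmda,tau_gaba,tau_thr Time constants (ms).
#' @param u_leak,u_exc,u_inh Reversal potentials (mV).
#' @param theta_rest Resting threshold (mV).
#' @param delta_theta Threshold jump per spike (mV, default 100).
#' @param axonal_delay Spike delivery delay (ms, default 0.8).
#' @param dt Simulation step (ms, default 0.1).
#' @return An object of class `lif_params` (internally converted to
#'   seconds).
#' @export
lif_params <- function(tau_mem = 20, tau_ampa = 5, tau_nmda = 100,
                       tau_gaba = 10, tau_thr = 5, u_leak = -70, u_exc = 0,
                       u_inh = -80, theta_rest = -50, delta_theta = 100,
                       axonal_delay = 0.8, dt = 0.1) {
  taus <- c(tau_mem, tau_ampa, tau_nmda, tau_gaba, tau_thr)
  stopifnot(all(taus > 0), dt > 0)
  if (dt >= min(taus)) stop("'dt' must be smaller than the smallest time constant")
  structure(list(tau_mem = tau_mem / 1e3, tau_ampa = tau_ampa / 1e3,
                 tau_nmda = tau_nmda / 1e3, tau_gaba = tau_gaba / 1e3,
                 tau_thr = tau_thr / 1e3, u_leak = u_leak, u_exc = u_exc,
                 u_inh = u_inh, theta_rest = theta_rest,
                 delta_theta = delta_theta, axonal_delay = axonal_delay / 1e3,
                 dt = dt / 1e3),
            class = "lif_params")
}

#' Spiking LPL rule parameters
#'
#' The spiking rule multiplies an alpha-filtered synaptic eligibility
#' (epsilon-filtered presynaptic spikes times the surrogate voltage
#' derivative) with an alpha-filtered postsynaptic error combining the
#' predictive term `-(S_i(t) - S_i(t - pred_delay))` and the
#' variance-modulated Hebbian term `lambda / (sigma_i^2 + xi) (S_i - Sbar_i)`,
#' plus a small transmitter-triggered potentiation per presynaptic spike.
#'
#' @param eta Learning rate (default 1e-2).
#' @param xi Variance floor (default 1e-3).
#' @param delta Transmitter-triggered potentiation per pre spike
#'   (default 1e-5).
#' @param lambda Hebbian strength (default 1; 0 disables the Hebbian term).
#' @param beta Surrogate-derivative steepness (1/mV, default 1).
#' @param pred_delay Prediction horizon (ms, default 20).
#' @param tau_mean,tau_var Time constants of the slow postsynaptic mean and
#'   variance (s; defaults 600 and 20).
#' @param tau_rate Time constant of the auxiliary instantaneous-rate
#'   estimate feeding the moment updates (ms, default 2000); needed because
#'   the squared deviation of a bare spike train is undefined, and chosen
#'   slow enough that sigma^2 tracks rate modulations rather than spike
#'   shot noise.
#' @param tau_alpha_rise,tau_alpha_fall Error/eligibility filter kernel
#'   (ms; defaults 2 and 10).
#' @param tau_eps_rise,tau_eps_fall Presynaptic (PSP-shaped) kernel
#'   (ms; defaults 5 and 20).
#' @param w_min,w_max Hard weight bounds for input synapses.
#' @param dt_plast Sub-grid for the per-synapse eligibility filters (ms,
#'   default 1; reduce to `dt` for exact filtering in small tests).
#' @param burn_in Time (s, default 0) during which input->E weights are
#'   frozen while membrane dynamics, inhibitory plasticity and the slow
#'   moment estimates run; desk-scale runs use this to reach the
#'   homeostatic operating point that a long simulation reaches on its own
#'   before input plasticity starts measuring prediction errors.
#' @param sbar_init,sigma2_init Initial slow moments (Hz and Hz^2).
#' @param pred_on Include the predictive term (default `TRUE`).
#' @param on Master switch for input->E plasticity.
#' @return An object of class `spiking_lpl_params` (times in seconds).
#' @export
spiking_lpl_params <- function(eta = 1e-2, xi = 1e-3, delta = 1e-5,
                               lambda = 1, beta = 1, pred_delay = 20,
                               tau_mean = 600, tau_var = 20, tau_rate = 2000,
                               tau_alpha_rise = 2, tau_alpha_fall = 10,
                               tau_eps_rise = 5, tau_eps_fall = 20,
                               w_min = 0, w_max = 1, dt_plast = 1,
                               sbar_init = 5, sigma2_init = 1,
                               burn_in = 0, pred_on = TRUE, on = TRUE) {
  stopifnot(eta >= 0, xi > 0, delta >= 0, beta > 0, pred_delay > 0)
  structure(list(eta = eta, xi = xi, delta = delta, lambda = lambda,
                 beta = beta, pred_delay = pred_delay / 1e3,
                 tau_mean = tau_mean, tau_var = tau_var,
                 tau_rate = tau_rate / 1e3,
                 tau_alpha_rise = tau_alpha_rise / 1e3,
                 tau_alpha_fall = tau_alpha_fall / 1e3,
                 tau_eps_rise = tau_eps_rise / 1e3,
                 tau_eps_fall = tau_eps_fall / 1e3,
                 w_min = w_min, w_max = w_max, dt_plast = dt_plast / 1e3,
                 sbar_init = sbar_init, sigma2_init = sigma2_init,
                 burn_in = burn_in, pred_on = pred_on, on = on),
            class = "spiking_lpl_params")
}

#' Inhibitory STDP parameters
#'
#' Pair-based inhibitory plasticity with a homeostatic rate target: each
#' post (excitatory) spike potentiates by the presynaptic trace, each pre
#' (inhibitory) spike changes the weight by `zeta * (x_post - 2 kappa tau)`,
#' giving a fixed point of the postsynaptic rate at `kappa`. The printed
#' all-potentiating variant (`+ 2 kappa tau`) is available for comparison
#' via `literal_printed = TRUE`.
#'
#' @param tau_stdp Trace time constant (ms, default 20).
#' @param zeta Learning rate (default 1e-3).
#' @param kappa Target excitatory rate (Hz, default 10).
#' @param w_inh_max Upper bound on I->E weights.
#' @param literal_printed Use the printed sign convention.
#' @param on Master switch.
#' @return An object of class `inh_stdp_params` (times in seconds).
#' @export
inh_stdp_params <- function(tau_stdp = 20, zeta = 1e-3, kappa = 10,
                            w_inh_max = 50, literal_printed = FALSE,
                            on = TRUE) {
  stopifnot(tau_stdp > 0, zeta >= 0, kappa > 0)
  structure(list(tau_stdp = tau_stdp / 1e3, zeta = zeta, kappa = kappa,
                 w_inh_max = w_inh_max, literal_printed = literal_printed,
                 on = on),
            class = "inh_stdp_params")
}

#' Network topology and initial weights
#'
#' Sparse random connectivity per pathway, except excitatory-to-inhibitory
#' connections which follow a Gaussian probability profile
#' `P(i <- j) = exp(-(j - c(i))^2 / sigma2)` with `c(i) = scale * i`
#' centred so each inhibitory neuron pools from a local group of excitatory
#' cells. Weights are nonnegative; signs enter through reversal potentials.
#'
#' @param n_input,n_exc,n_inh Population sizes (defaults 500/100/25).
#' @param p_in_e,p_in_i,p_i_e,p_i_i Connection probabilities.
#' @param w_in_e,w_in_i,w_e_i,w_i_e,w_i_i Initial weights per pathway.
#' @param ei_scale,ei_sigma2 Gaussian E->I profile parameters
#'   (`c(i) = ei_scale * i`, variance `ei_sigma2`); the default scale 0.25
#'   matches a 4:1 E:I ratio.
#' @return An object of class `network_topology`.
#' @export
network_topology <- function(n_input = 500L, n_exc = 100L, n_inh = 25L,
                             p_in_e = 0.5, p_in_i = 0.5, p_i_e = 0.8,
                             p_i_i = 0.5, w_in_e = 0.2, w_in_i = 0.2,
                             w_e_i = 0.4, w_i_e = 0.3, w_i_i = 1.5,
                             ei_scale = 0.25, ei_sigma2 = 20) {
  probs <- c(p_in_e, p_in_i, p_i_e, p_i_i)
  if (any(probs < 0 | probs > 1)) stop("connection probabilities must lie in [0, 1]")
  structure(list(n_input = as.integer(n_input), n_exc = as.integer(n_exc),
                 n_inh = as.integer(n_inh), p_in_e = p_in_e, p_in_i = p_in_i,
                 p_i_e = p_i_e, p_i_i = p_i_i, w_in_e = w_in_e,
                 w_in_i = w_in_i, w_e_i = w_e_i, w_i_e = w_i_e,
                 w_i_i = w_i_i, ei_scale = ei_scale, ei_sigma2 = ei_sigma2),
            class = "network_topology")
}

#' E->I Gaussian connection probability profile
#'
#' @param j Excitatory (presynaptic) index, 1-based.
#' @param i Inhibitory (postsynaptic) index, 1-based.
#' @param scale Centre slope (`c(i) = scale * i`).
#' @param sigma2 Profile variance.
#' @return Connection probability.
#' @export
ei_profile <- function(j, i, scale = 0.25, sigma2 = 20) {
  pmin(exp(-(j - scale * i)^2 / sigma2), 1)
}

#' Build the sparse network state
#'
#' @param topology A [network_topology()].
#' @param seed Integer seed.
#' @return A list of weight matrices and masks consumed by [run_snn()]:
#'   `w_in_e` (n_exc x n_input, plastic), `w_in_i`, `w_e_i` (Gaussian
#'   profile), `w_i_e` (plastic), `w_i_i`, plus the 0/1 masks `m_in_e`,
#'   `m_i_e` and the sizes.
#' @export
build_network <- function(topology, seed = 1L) {
  stopifnot(inherits(topology, "network_topology"))
  set.seed(seed)
  tp <- topology
  bern <- function(nr, nc, p) matrix(runif(nr * nc) < p, nr, nc) * 1L
  m_in_e <- bern(tp$n_exc, tp$n_input, tp$p_in_e)
  m_in_i <- bern(tp$n_inh, tp$n_input, tp$p_in_i)
  # Gaussian E->I profile: P(i <- j) = exp(-(j - c(i))^2 / sigma2)
  pj <- outer(seq_len(tp$n_inh), seq_len(tp$n_exc),
              function(i, j) ei_profile(j, i, tp$ei_scale, tp$ei_sigma2))
  m_e_i <- (matrix(runif(length(pj)), nrow = nrow(pj), ncol = ncol(pj)) < pj) * 1L
  m_i_e <- bern(tp$n_exc, tp$n_inh, tp$p_i_e)
  m_i_i <- bern(tp$n_inh, tp$n_inh, tp$p_i_i)
  diag(m_i_i) <- 0L # no self-connections
  list(n_in = tp$n_input, n_exc = tp$n_exc, n_inh = tp$n_inh,
       w_in_e = m_in_e * tp$w_in_e, w_in_i = m_in_i * tp$w_in_i,
       w_e_i = m_e_i * tp$w_e_i, w_i_e = m_i_e * tp$w_i_e,
       w_i_i = m_i_i * tp$w_i_i,
       m_in_e = m_in_e, m_i_e = m_i_e, topology = tp)
}

#' Run the spiking network simulation
#'
#' Fixed-step forward-Euler integration of the conductance-based LIF
#' network with optional spiking LPL on input->E synapses and inhibitory
#' STDP on I->E synapses.
#'
#' @param network Output of [build_network()] (weight matrices may be
#'   modified in place before the call, e.g. to ablate inhibition).
#' @param input Either a [spike_raster()] of input spikes or `NULL`.
#' @param duration Simulated time (s).
#' @param lif A [lif_params()].
#' @param lpl A [spiking_lpl_params()].
#' @param istdp An [inh_stdp_params()].
#' @param snapshot_times Times (s) at which to snapshot the plastic weights.
#' @param record Neuron ids (1-based; excitatory first) whose membrane,
#'   threshold and excitatory conductance are recorded every step.
#' @return A list: `raster` (network [spike_raster()] with `E` and `I`
#'   slices), final `w_in_e` and `w_i_e`, `snapshots`, slow moments `sbar`,
#'   `sigma2`, recorded traces, and `exc_rate` / `inh_rate` diagnostics
#'   (flagged unstable above `rate_ceiling`).
#' @param rate_ceiling Instability flag threshold (Hz, default 200).
#' @export
run_snn <- function(network, input, duration, lif = lif_params(),
                    lpl = spiking_lpl_params(), istdp = inh_stdp_params(),
                    snapshot_times = numeric(0), record = integer(0),
                    rate_ceiling = 200) {
  if (is.null(input)) {
    in_times <- numeric(0); in_ids <- integer(0)
  } else {
    stopifnot(inherits(input, "spike_raster"))
    in_times <- input$time; in_ids <- input$id
  }
  net <- network
  net$m_in_e <- matrix(as.integer(net$m_in_e), nrow(net$m_in_e))
  net$m_i_e <- matrix(as.integer(net$m_i_e), nrow(net$m_i_e))
  res <- cpp_run_lif_network(
    net, unclass(lif),
    c(unclass(lpl), list()), unclass(istdp),
    in_times, as.integer(in_ids), duration, lif$dt,
    as.numeric(snapshot_times), as.integer(record))
  n_exc <- network$n_exc; n_inh <- network$n_inh
  slices <- list(E = c(1L, n_exc))
  if (n_inh > 0) slices$I <- c(n_exc + 1L, n_exc + n_inh)
  raster <- spike_raster(res$spike_time, res$spike_id, duration = duration,
                         dt = lif$dt, population_slices = slices)
  exc_rate <- sum(res$spike_id <= n_exc) / (n_exc * duration)
  inh_rate <- if (n_inh > 0) sum(res$spike_id > n_exc) / (n_inh * duration) else NA_real_
  list(raster = raster, w_in_e = res$w_in_e, w_i_e = res$w_i_e,
       snapshots = res$snapshots, sbar = res$sbar, sigma2 = res$sigma2,
       rec_U = res$rec_U, rec_theta = res$rec_theta, rec_gexc = res$rec_gexc,
       exc_rate = exc_rate, inh_rate = inh_rate,
       unstable = isTRUE(exc_rate > rate_ceiling))
}

#' Double-exponential causal filter
#'
#' Cascade of two leaky integrators with unit DC gain:
#' `tau_rise dc1/dt = -c1 + x`, `tau_fall dc2/dt = -c2 + c1`.
#'
#' @param x Input series.
#' @param tau_rise,tau_fall Time constants (same unit as `dt`).
#' @param dt Step size.
#' @return Filtered series of the same length.
#' @export
double_exp_filter <- function(x, tau_rise, tau_fall, dt) {
  stopifnot(tau_rise > 0, tau_fall > 0, dt > 0)
  cpp_double_exp_filter(as.numeric(x), tau_rise, tau_fall, dt)
}

#' Build the five-population input ensemble of the predictive-coding
#' experiment
#'
#' P0: constant `base_rate`; P1/P2: slow Fourier signals with periods T and
#' T + 1/13 s (incommensurate, avoiding phase locking); P1_ctl/P2_ctl:
#' temporally shuffled versions of P1/P2.
#'
#' @param n_per_group Neurons per population.
#' @param duration Raster duration (s).
#' @param base_rate Centre rate (Hz, default 5).
#' @param period Period of P1 (s, default 3).
#' @param dt Thinning step (s, default 1e-4).
#' @param seed Integer seed.
#' @return List with the input `raster`, the rate `traces` and the group
#'   `slices`.
#' @export
make_snn_inputs <- function(n_per_group = 100L, duration = 100,
                            base_rate = 5, period = 3, dt = 1e-4, seed = 1L) {
  set.seed(seed)
  p1 <- gen_slow_signal(slow_signal_config(period = period, base_rate = base_rate))
  p2 <- gen_slow_signal(slow_signal_config(period = period + 1 / 13,
                                           base_rate = base_rate))
  p1c <- make_shuffled_control(p1)
  p2c <- make_shuffled_control(p2)
  p0 <- structure(rep(base_rate, length(p1)), dt = attr(p1, "dt"))
  traces <- list(P0 = p0, P1 = p1, P2 = p2, P1_ctl = p1c, P2_ctl = p2c)
  raster <- gen_poisson_raster(traces, rep(n_per_group, 5L), duration,
                               dt = dt, group_names = names(traces))
  list(raster = raster, traces = traces,
       slices = raster$population_slices)
}

#' Mean afferent weight per excitatory neuron and input population
#'
#' @param w_in_e Final input->E weight matrix from [run_snn()].
#' @param mask Connectivity mask `m_in_e`.
#' @param slices Named population slices over input ids.
#' @return Matrix (n_exc x populations) of mean weights over existing
#'   synapses.
#' @export
mean_afferent_weights <- function(w_in_e, mask, slices) {
  out <- sapply(slices, function(sl) {
    cols <- sl[1]:sl[2]
    num <- rowSums(w_in_e[, cols, drop = FALSE] * mask[, cols, drop = FALSE])
    den <- rowSums(mask[, cols, drop = FALSE])
    ifelse(den > 0, num / den, 0)
  })
  matrix(out, nrow = nrow(w_in_e), dimnames = list(NULL, names(slices)))
}

#' Run the full slow-signal SNN experiment
#'
#' Wires the five-population Poisson inputs into the recurrent network and
#' runs LPL plus inhibitory plasticity, with the ablations of the reference
#' experiments.
#'
#' @param duration Simulated time (s).
#' @param n_per_group Input neurons per population.
#' @param n_exc,n_inh Network sizes (desk-scale defaults 50/12; the
#'   full-size experiment uses 100/25 with 100 per input group).
#' @param ablation One of `"full"`, `"pred_off"`, `"hebb_off"`,
#'   `"inhib_off"`, `"inhib_fixed"`.
#' @param eta Spiking LPL learning rate for the run (desk-scale default 0.1
#'   compensates runs ~300x shorter than the reference's 28 h; use 1e-2 at
#'   full scale).
#' @param seed Integer seed.
#' @param snapshot_times,record Passed to [run_snn()].
#' @return The [run_snn()] result plus `inputs`, `network`, `afferents`
#'   (mean weights per population) and per-neuron `selectivity` for P1/P2.
#' @export
snn_experiment <- function(duration = 300, n_per_group = 40L, n_exc = 50L,
                           n_inh = 12L, ablation = c("full", "pred_off",
                                                     "hebb_off", "inhib_off",
                                                     "inhib_fixed"),
                           eta = 0.1, seed = 1L,
                           snapshot_times = numeric(0), record = integer(0)) {
  ablation <- match.arg(ablation)
  inputs <- make_snn_inputs(n_per_group, duration, seed = seed)
  topo <- network_topology(n_input = 5L * n_per_group, n_exc = n_exc,
                           n_inh = if (ablation == "inhib_off") 0L else n_inh)
  network <- build_network(topo, seed = seed + 1L)
  # desk-scale operating point: slow moments initialised at the homeostatic
  # target and compressed in time, burn-in before input plasticity, weight
  # floor keeping the disinhibited network excitable (methods vignette)
  lpl <- spiking_lpl_params(eta = eta, burn_in = min(100, duration / 3),
                            tau_rate = 5e3, tau_mean = 60, tau_var = 10,
                            w_min = 0.1, sbar_init = 10, sigma2_init = 1,
                            pred_on = ablation != "pred_off",
                            lambda = if (ablation == "hebb_off") 0 else 1)
  istdp <- inh_stdp_params(on = !(ablation %in% c("inhib_off", "inhib_fixed")))
  res <- run_snn(network, inputs$raster, duration, lpl = lpl, istdp = istdp,
                 snapshot_times = snapshot_times, record = record)
  aff <- mean_afferent_weights(res$w_in_e, network$m_in_e, inputs$slices)
  res$inputs <- inputs
  res$network <- network
  res$afferents <- aff
  res$selectivity <- cbind(
    P1 = signal_selectivity(aff[, "P1"], aff[, "P1_ctl"]),
    P2 = signal_selectivity(aff[, "P2"], aff[, "P2_ctl"]))
  res$ablation <- ablation
  res
}
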