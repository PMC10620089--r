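#' STDP pairing protocol specification
#'
#' A single clamped postsynaptic neuron receives `n_pairings` pre/post spike
#' pairs with relative timing `delta_t` (positive: pre before post) at
#' repetition frequency `rho`, while its membrane is held at `clamp_voltage`
#' between forced spikes. The slow metaplastic state (running rate mean and
#' variance) is set by `sbar_init` / `sigma2_init` and is frozen during the
#' protocol by default: the protocol probes plasticity *given* a metaplastic
#' state, and with `evolve_moments = TRUE` the variance estimate climbs
#' within the first pairings (its input is the squared deviation of the
#' clamped neuron's own forced firing) and erases the configured state.
#'
#' @param delta_t Pre-post delay in ms, in `[-50, 50]`.
#' @param rho Repetition frequency (Hz, default 10).
#' @param n_pairings Number of pairings (default 100).
#' @param clamp_voltage Holding potential (mV, default -51).
#' @param w_init Initial synaptic weight (default 0.5).
#' @param eta Protocol learning rate (default 5e-3).
#' @param sigma2_init Initial variance estimate (default 0.1).
#' @param sbar_init Initial rate mean (Hz); default `rho`, the neuron's
#'   long-run firing rate under the protocol (self-consistent adaptation).
#' @param evolve_moments Let the slow moments evolve (default `FALSE`).
#' @param pre_spikes,post_spikes Deliver the pre / inject the post spikes
#'   (default `TRUE`; disabling one isolates the transmitter-triggered or
#'   error-gated pathway).
#' @return An object of class `pairing_protocol`.
#' @export
pairing_protocol <- function(delta_t, rho = 10, n_pairings = 100L,
                             clamp_voltage = -51, w_init = 0.5, eta = 5e-3,
                             sigma2_init = 0.1, sbar_init = rho,
                             evolve_moments = FALSE, pre_spikes = TRUE,
                             post_spikes = TRUE) {
  stopifnot(n_pairings >= 0, rho > 0)
  if (abs(delta_t) >= 1000 / rho)
    stop("|delta_t| must be smaller than the pairing period")
  structure(list(delta_t = delta_t, rho = rho,
                 n_pairings = as.integer(n_pairings),
                 clamp_voltage = clamp_voltage, w_init = w_init, eta = eta,
                 sigma2_init = sigma2_init, sbar_init = sbar_init,
                 evolve_moments = evolve_moments, pre_spikes = pre_spikes,
                 post_spikes = post_spikes),
            class = "pairing_protocol")
}

#' Run one STDP induction protocol
#'
#' Simulates the spiking LPL rule on a single synapse under the clamped
#' pairing protocol and reports the relative weight change. Fully
#' deterministic given the protocol (no randomness).
#'
#' @param protocol A [pairing_protocol()].
#' @param lpl A [spiking_lpl_params()] supplying the rule constants (its
#'   `eta`, `sbar_init`, `sigma2_init` are overridden by the protocol).
#' @param lif A [lif_params()] (supplies `theta_rest` and `dt`).
#' @return List with `rel_change` (`(w_final - w_init) / w_init`),
#'   `w_final` and the final slow moments.
#' @export
run_pairing_protocol <- function(protocol, lpl = spiking_lpl_params(),
                                 lif = lif_params()) {
  stopifnot(inherits(protocol, "pairing_protocol"))
  if (protocol$n_pairings > 0 &&
      abs(protocol$delta_t) > 0 && abs(protocol$delta_t) / 1e3 < lif$dt)
    stop("forced pre and post spikes overlap within one time step")
  res <- cpp_pairing_protocol(
    protocol$delta_t / 1e3, protocol$rho, protocol$n_pairings,
    protocol$w_init, protocol$eta, unclass(lpl), protocol$clamp_voltage,
    lif$theta_rest, protocol$sbar_init, protocol$sigma2_init,
    protocol$evolve_moments, lif$dt, protocol$pre_spikes,
    protocol$post_spikes)
  res
}

#' STDP window: relative weight change versus pre-post timing
#'
#' One protocol run per `delta_t`, all starting from the same metaplastic
#' state.
#'
#' @param delta_t_grid Timings in ms.
#' @param sigma2_init,sbar_init Initial metaplastic state.
#' @param rho Repetition frequency (Hz).
#' @param ... Passed to [pairing_protocol()].
#' @param lpl,lif See [run_pairing_protocol()].
#' @return A data frame (class `stdp_curve`) with columns `delta_t` and
#'   `dw_rel`.
#' @export
stdp_window_sweep <- function(delta_t_grid, sigma2_init = 0.1,
                              sbar_init = 10, rho = 10, ...,
                              lpl = spiking_lpl_params(), lif = lif_params()) {
  dw <- vapply(delta_t_grid, function(dtms) {
    pr <- pairing_protocol(dtms, rho = rho, sigma2_init = sigma2_init,
                           sbar_init = sbar_init, ...)
    run_pairing_protocol(pr, lpl, lif)$rel_change
  }, numeric(1))
  structure(data.frame(delta_t = delta_t_grid, dw_rel = dw),
            class = c("stdp_curve", "data.frame"))
}

#' Rate dependence of plasticity: weight change versus repetition frequency
#'
#' @param rho_grid Repetition frequencies (Hz).
#' @param delta_t Fixed timing (ms, default +10).
#' @param sigma2_init,sbar_init Initial metaplastic state (defaults 0.1 and
#'   20 Hz, the reference's frequency-sweep condition).
#' @param ... Passed to [pairing_protocol()].
#' @param lpl,lif See [run_pairing_protocol()].
#' @return A data frame (class `stdp_curve`) with columns `rho` and
#'   `dw_rel`.
#' @export
frequency_sweep <- function(rho_grid, delta_t = 10, sigma2_init = 0.1,
                            sbar_init = 20, ...,
                            lpl = spiking_lpl_params(), lif = lif_params()) {
  dw <- vapply(rho_grid, function(r) {
    pr <- pairing_protocol(delta_t, rho = r, sigma2_init = sigma2_init,
                           sbar_init = sbar_init, ...)
    run_pairing_protocol(pr, lpl, lif)$rel_change
  }, numeric(1))
  structure(data.frame(rho = rho_grid, dw_rel = dw),
            class = c("stdp_curve", "data.frame"))
}
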