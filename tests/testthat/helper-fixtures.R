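# Shared fixtures built in code; everything is seeded and small.

tiny_batch <- function(B = 4, N = 3, seed = 11) {
  set.seed(seed)
  paired_batch(matrix(rnorm(B * N), B, N), matrix(rnorm(B * N), B, N))
}

# numerical gradient of the LPL objective with proper stop-gradients
numerical_lpl_grad <- function(layer, batch, eps = 1e-6) {
  upd <- lpl_weight_update(layer, batch)
  zbar <- upd$moments$zbar
  zp <- upd$z_prev
  g <- layer$W * 0
  for (i in seq_len(nrow(g))) for (j in seq_len(ncol(g))) {
    lp <- layer; lp$W[i, j] <- lp$W[i, j] + eps
    lm <- layer; lm$W[i, j] <- lm$W[i, j] - eps
    g[i, j] <- (lpl_loss(lp, batch, zbar, zp) -
                lpl_loss(lm, batch, zbar, zp)) / (2 * eps)
  }
  g
}

# one-input one-neuron network driven by a single spike; used by LIF tests
single_neuron_net <- function(w = 0.5, seed = 1) {
  topo <- network_topology(n_input = 1L, n_exc = 1L, n_inh = 0L,
                           p_in_e = 1, w_in_e = w)
  build_network(topo, seed = seed)
}

quiet_lpl <- function(...) spiking_lpl_params(on = FALSE, ...)
quiet_istdp <- function(...) inh_stdp_params(on = FALSE, ...)
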