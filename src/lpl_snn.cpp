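#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// All times in seconds, voltages in mV, conductances in units of the leak
// conductance. Spike trains are sums of Dirac deltas; a delta of weight A
// entering a leaky integrator tau*dc/dt = -c + s makes c jump by A/tau.

// ---------------------------------------------------------------------------
// Inhomogeneous Poisson raster by per-step Bernoulli thinning (rate*dt << 1).
// rates: n_groups x n_bins piecewise-constant rate traces (Hz) on a grid of
// width bin_dt; group: 0-based group index per neuron.
// [[Rcpp::export]]
List cpp_gen_poisson_raster(NumericMatrix rates, IntegerVector group,
                            double bin_dt, double dt, double duration) {
  const int n_neurons = group.size();
  const int n_groups = rates.nrow();
  const int n_bins = rates.ncol();
  const long n_steps = (long)std::llround(duration / dt);
  std::vector<double> times;
  std::vector<int> ids;
  std::vector<double> p(n_groups);
  long bin_prev = -1;
  for (long s = 0; s < n_steps; ++s) {
    double t = s * dt;
    long bin = (long)(t / bin_dt);
    if (bin >= n_bins) bin = n_bins - 1;
    if (bin != bin_prev) {
      for (int g = 0; g < n_groups; ++g) p[g] = rates(g, bin) * dt;
      bin_prev = bin;
    }
    for (int i = 0; i < n_neurons; ++i) {
      if (unif_rand() < p[group[i]]) {
        times.push_back(t);
        ids.push_back(i + 1); // 1-based neuron ids on the R side
      }
    }
  }
  return List::create(_["time"] = wrap(times), _["id"] = wrap(ids));
}

// ---------------------------------------------------------------------------
// Double-exponential causal filter: cascade of two leaky integrators
// tau_rise * dc1/dt = -c1 + x ; tau_fall * dc2/dt = -c2 + c1 (unit DC gain).
// [[Rcpp::export]]
NumericVector cpp_double_exp_filter(NumericVector x, double tau_rise,
                                    double tau_fall, double dt) {
  const int n = x.size();
  NumericVector out(n);
  double c1 = 0.0, c2 = 0.0;
  for (int s = 0; s < n; ++s) {
    c1 += dt / tau_rise * (-c1 + x[s]);
    c2 += dt / tau_fall * (-c2 + c1);
    out[s] = c2;
  }
  return out;
}

static inline double surrogate_fprime(double U, double theta_rest, double beta) {
  double d = 1.0 + beta * std::fabs(U - theta_rest);
  return beta / (d * d);
}

// ---------------------------------------------------------------------------
// Conductance-based LIF network with spiking LPL on input->E synapses and
// inhibitory STDP on I->E synapses.
//
// Pathways (dense weight matrices, n_post x n_pre, with 0/1 masks):
//   W_in_e (plastic, LPL), W_in_i, W_e_i, W_i_e (plastic, iSTDP), W_i_i.
// Neuron ids: 0..n_exc-1 excitatory, n_exc..n_exc+n_inh-1 inhibitory.
// [[Rcpp::export]]
List cpp_run_lif_network(List net, List lif, List lpl, List istdp,
                         NumericVector in_times, IntegerVector in_ids,
                         double duration, double dt,
                         NumericVector snapshot_times,
                         IntegerVector record_ids) {
  // --- unpack topology -----------------------------------------------------
  const int n_in  = as<int>(net["n_in"]);
  const int n_exc = as<int>(net["n_exc"]);
  const int n_inh = as<int>(net["n_inh"]);
  NumericMatrix W_in_e = clone(as<NumericMatrix>(net["w_in_e"]));
  NumericMatrix W_in_i = as<NumericMatrix>(net["w_in_i"]);
  NumericMatrix W_e_i  = as<NumericMatrix>(net["w_e_i"]);
  NumericMatrix W_i_e  = clone(as<NumericMatrix>(net["w_i_e"]));
  NumericMatrix W_i_i  = as<NumericMatrix>(net["w_i_i"]);
  IntegerMatrix M_in_e = as<IntegerMatrix>(net["m_in_e"]);
  IntegerMatrix M_i_e  = as<IntegerMatrix>(net["m_i_e"]);

  // --- unpack LIF params ---------------------------------------------------
  const double tau_mem  = as<double>(lif["tau_mem"]);
  const double tau_ampa = as<double>(lif["tau_ampa"]);
  const double tau_nmda = as<double>(lif["tau_nmda"]);
  const double tau_gaba = as<double>(lif["tau_gaba"]);
  const double tau_thr  = as<double>(lif["tau_thr"]);
  const double U_leak   = as<double>(lif["u_leak"]);
  const double U_exc    = as<double>(lif["u_exc"]);
  const double U_inh    = as<double>(lif["u_inh"]);
  const double theta_rest = as<double>(lif["theta_rest"]);
  const double delta_theta = as<double>(lif["delta_theta"]);
  const double axonal_delay = as<double>(lif["axonal_delay"]);

  // --- unpack spiking LPL params ------------------------------------------
  const bool   lpl_on   = as<bool>(lpl["on"]);
  const bool   pred_on  = as<bool>(lpl["pred_on"]);
  const double lambda   = as<double>(lpl["lambda"]);
  const double eta      = as<double>(lpl["eta"]);
  const double xi       = as<double>(lpl["xi"]);
  const double delta_tt = as<double>(lpl["delta"]);
  const double beta     = as<double>(lpl["beta"]);
  const double pred_delay = as<double>(lpl["pred_delay"]);
  const double tau_mean = as<double>(lpl["tau_mean"]);
  const double tau_var  = as<double>(lpl["tau_var"]);
  const double tau_rate = as<double>(lpl["tau_rate"]);
  const double tau_a_r  = as<double>(lpl["tau_alpha_rise"]);
  const double tau_a_f  = as<double>(lpl["tau_alpha_fall"]);
  const double tau_e_r  = as<double>(lpl["tau_eps_rise"]);
  const double tau_e_f  = as<double>(lpl["tau_eps_fall"]);
  const double w_min    = as<double>(lpl["w_min"]);
  const double w_max    = as<double>(lpl["w_max"]);
  const double dt_plast = as<double>(lpl["dt_plast"]);
  const double sbar0    = as<double>(lpl["sbar_init"]);
  const double sigma20  = as<double>(lpl["sigma2_init"]);
  const double burn_in  = as<double>(lpl["burn_in"]);

  // --- unpack inhibitory STDP params --------------------------------------
  const bool   istdp_on = as<bool>(istdp["on"]);
  const bool   istdp_literal = as<bool>(istdp["literal_printed"]);
  const double tau_stdp = as<double>(istdp["tau_stdp"]);
  const double zeta     = as<double>(istdp["zeta"]);
  const double kappa    = as<double>(istdp["kappa"]);
  const double w_inh_max = as<double>(istdp["w_inh_max"]);

  const long n_steps = (long)std::llround(duration / dt);
  const int n_net = n_exc + n_inh;
  const int delay_steps = std::max(1, (int)std::lround(axonal_delay / dt));
  const int pred_steps = std::max(1, (int)std::lround(pred_delay / dt));
  const int n_sub = std::max(1, (int)std::lround(dt_plast / dt));
  const double dt_p = n_sub * dt;
  const long burn_steps = (long)std::llround(burn_in / dt);

  // --- state ---------------------------------------------------------------
  std::vector<double> U(n_net, U_leak), theta(n_net, theta_rest);
  std::vector<double> g_ampa(n_net, 0.0), g_nmda(n_net, 0.0), g_gaba(n_net, 0.0);

  // delay ring: spikes emitted at step s are delivered at step s + delay_steps
  const int ring_len = delay_steps + 1;
  std::vector< std::vector<int> > ring(ring_len); // ids: net 0..n_net-1, input n_net + j

  // LPL per-E-neuron state
  std::vector<double> srate(n_exc, sbar0);         // filtered instantaneous rate
  std::vector<double> sbar(n_exc, sbar0), sigma2(n_exc, sigma20);
  std::vector<double> err1(n_exc, 0.0), err2(n_exc, 0.0); // alpha-filtered error
  std::vector<unsigned char> pred_ring((size_t)n_exc * pred_steps, 0);
  int pred_pos = 0;
  // presynaptic epsilon traces (per input neuron)
  std::vector<double> u1(n_in, 0.0), u2(n_in, 0.0);
  // per-synapse eligibility (alpha-filtered u_j * f'(U_i)), dense n_exc x n_in
  std::vector<double> el1, el2;
  if (lpl_on) { el1.assign((size_t)n_exc * n_in, 0.0); el2.assign((size_t)n_exc * n_in, 0.0); }

  // iSTDP traces
  std::vector<double> x_e(n_exc, 0.0), x_i(n_inh, 0.0);
  const double istdp_offset = 2.0 * kappa * tau_stdp;

  // recording
  std::vector<double> spk_t; std::vector<int> spk_id;
  const int n_rec = record_ids.size();
  NumericMatrix rec_U(n_rec > 0 ? n_steps : 0, n_rec);
  NumericMatrix rec_theta(n_rec > 0 ? n_steps : 0, n_rec);
  NumericMatrix rec_gexc(n_rec > 0 ? n_steps : 0, n_rec);
  List snapshots(snapshot_times.size());
  int snap_idx = 0;

  const double k_mem = dt / tau_mem, k_ampa = dt / tau_ampa,
               k_nmda = dt / tau_nmda, k_gaba = dt / tau_gaba,
               k_thr = dt / tau_thr, k_stdp = dt / tau_stdp,
               k_rate = dt / tau_rate, k_mean = dt / tau_mean,
               k_var = dt / tau_var, k_ar = dt / tau_a_r, k_af = dt / tau_a_f,
               k_er = dt / tau_e_r, k_ef = dt / tau_e_f;

  long ev = 0; // pointer into sorted input events
  const long n_ev = in_times.size();

  for (long s = 0; s < n_steps; ++s) {
    const double t = s * dt;
    const int emit_slot = (int)((s + delay_steps) % ring_len);

    // 1. queue input spikes emitted in [t, t+dt) for delayed delivery
    while (ev < n_ev && in_times[ev] < t + dt) {
      ring[emit_slot].push_back(n_net + (in_ids[ev] - 1));
      ++ev;
    }

    // 2. deliver spikes scheduled for this step (emitted delay_steps ago)
    std::vector<int>& due = ring[(int)(s % ring_len)];
    for (size_t q = 0; q < due.size(); ++q) {
      const int id = due[q];
      if (id >= n_net) {                       // input spike
        const int j = id - n_net;
        for (int i = 0; i < n_exc; ++i)
          if (M_in_e(i, j)) {
            g_ampa[i] += W_in_e(i, j);
            if (lpl_on && s >= burn_steps) {    // transmitter-triggered term
              double w = W_in_e(i, j) + eta * delta_tt;
              W_in_e(i, j) = (w > w_max) ? w_max : w;
            }
          }
        for (int i = 0; i < n_inh; ++i)
          if (W_in_i(i, j) > 0.0) g_ampa[n_exc + i] += W_in_i(i, j);
        u1[j] += 1.0 / tau_e_r;                 // presynaptic epsilon trace
      } else if (id < n_exc) {                  // excitatory network spike
        for (int i = 0; i < n_inh; ++i)
          if (W_e_i(i, id) > 0.0) g_ampa[n_exc + i] += W_e_i(i, id);
      } else {                                  // inhibitory network spike
        const int j = id - n_exc;
        for (int i = 0; i < n_exc; ++i)
          if (M_i_e(i, j)) g_gaba[i] += W_i_e(i, j);
        for (int i = 0; i < n_inh; ++i)
          if (W_i_i(i, j) > 0.0) g_gaba[n_exc + i] += W_i_i(i, j);
      }
    }
    due.clear();

    // 3. integrate membrane, conductances, thresholds (forward Euler)
    for (int i = 0; i < n_net; ++i) {
      const double g_exc = 0.5 * (g_ampa[i] + g_nmda[i]);
      U[i] += k_mem * ((U_leak - U[i]) + g_exc * (U_exc - U[i]) +
                       g_gaba[i] * (U_inh - U[i]));
      g_nmda[i] += k_nmda * (g_ampa[i] - g_nmda[i]);
      g_ampa[i] -= k_ampa * g_ampa[i];
      g_gaba[i] -= k_gaba * g_gaba[i];
      theta[i] += k_thr * (theta_rest - theta[i]);
    }

    // 4. spike detection and spike-triggered plasticity (emission times)
    for (int i = 0; i < n_net; ++i) {
      if (U[i] >= theta[i]) {
        theta[i] += delta_theta;
        spk_t.push_back(t); spk_id.push_back(i + 1);
        ring[emit_slot].push_back(i);
        if (i < n_exc) {
          pred_ring[(size_t)i * pred_steps + pred_pos] |= 2; // current spike
          srate[i] += 1.0 / tau_rate;
          x_e[i] += 1.0;
          if (istdp_on)
            for (int j = 0; j < n_inh; ++j)
              if (M_i_e(i, j)) {
                double w = W_i_e(i, j) + zeta * x_i[j];
                W_i_e(i, j) = (w > w_inh_max) ? w_inh_max : w;
              }
        } else {
          const int j = i - n_exc;
          x_i[j] += 1.0;
          if (istdp_on)
            for (int ii = 0; ii < n_exc; ++ii)
              if (M_i_e(ii, j)) {
                double pre_term = istdp_literal ? (x_e[ii] + istdp_offset)
                                                : (x_e[ii] - istdp_offset);
                double w = W_i_e(ii, j) + zeta * pre_term;
                if (w < 0.0) w = 0.0; else if (w > w_inh_max) w = w_inh_max;
                W_i_e(ii, j) = w;
              }
        }
      }
    }

    // 5. trace updates
    for (int i = 0; i < n_exc; ++i) x_e[i] -= k_stdp * x_e[i];
    for (int j = 0; j < n_inh; ++j) x_i[j] -= k_stdp * x_i[j];

    if (lpl_on) {
      for (int j = 0; j < n_in; ++j) {
        u1[j] -= k_er * u1[j];
        u2[j] += k_ef * (u1[j] - u2[j]);
      }
      for (int i = 0; i < n_exc; ++i) {
        // instantaneous error: deltas from current & 20-ms-delayed own spikes
        // plus smooth Hebbian baseline -(lambda/(sigma^2+xi)) * sbar
        const size_t base = (size_t)i * pred_steps;
        unsigned char flags = pred_ring[base + pred_pos];
        double coef = lambda / (sigma2[i] + xi);
        double delta_w_err = 0.0;
        if (flags & 2) delta_w_err += (pred_on ? -1.0 : 0.0) + coef;
        if (flags & 1) delta_w_err += (pred_on ? 1.0 : 0.0);
        err1[i] += k_ar * (-err1[i] - coef * sbar[i]) + delta_w_err / tau_a_r;
        err2[i] += k_af * (err1[i] - err2[i]);
        // slow moments from the filtered rate estimate
        double dev = srate[i] - sbar[i];
        sbar[i] += k_mean * dev;
        sigma2[i] += k_var * (dev * dev - sigma2[i]);
        srate[i] -= k_rate * srate[i];
        // shift delayed-spike flag: current spike becomes the Delta-t-old one
        // once the ring wraps; store current bit into position for reuse
        pred_ring[base + pred_pos] = (flags & 2) ? 1 : 0;
      }
      pred_pos = (pred_pos + 1) % pred_steps;

      // 6. per-synapse eligibility and weight drift on the plasticity sub-grid
      if (s % n_sub == 0) {
        const bool learn = s >= burn_steps;
        for (int i = 0; i < n_exc; ++i) {
          const double vi = surrogate_fprime(U[i], theta_rest, beta);
          const double Ei = err2[i];
          double* e1 = &el1[(size_t)i * n_in];
          double* e2 = &el2[(size_t)i * n_in];
          for (int j = 0; j < n_in; ++j) {
            if (!M_in_e(i, j)) continue;
            e1[j] += dt_p / tau_a_r * (-e1[j] + u2[j] * vi);
            e2[j] += dt_p / tau_a_f * (e1[j] - e2[j]);
            if (!learn) continue;
            double w = W_in_e(i, j) + eta * e2[j] * Ei * dt_p;
            if (w < w_min) w = w_min; else if (w > w_max) w = w_max;
            W_in_e(i, j) = w;
          }
        }
      }
    } else {
      pred_pos = (pred_pos + 1) % pred_steps;
    }

    // 7. recording
    for (int r = 0; r < n_rec; ++r) {
      const int i = record_ids[r] - 1;
      rec_U(s, r) = U[i];
      rec_theta(s, r) = theta[i];
      rec_gexc(s, r) = 0.5 * (g_ampa[i] + g_nmda[i]);
    }
    while (snap_idx < snapshot_times.size() && t + dt > snapshot_times[snap_idx]) {
      snapshots[snap_idx] = List::create(
        _["time"] = snapshot_times[snap_idx],
        _["w_in_e"] = clone(W_in_e), _["w_i_e"] = clone(W_i_e));
      ++snap_idx;
    }
    if (s % 200000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["spike_time"] = wrap(spk_t), _["spike_id"] = wrap(spk_id),
    _["w_in_e"] = W_in_e, _["w_i_e"] = W_i_e,
    _["snapshots"] = snapshots,
    _["sbar"] = wrap(sbar), _["sigma2"] = wrap(sigma2),
    _["rec_U"] = rec_U, _["rec_theta"] = rec_theta, _["rec_gexc"] = rec_gexc);
}

// ---------------------------------------------------------------------------
// STDP induction protocol on a single clamped neuron with one plastic synapse
// following the spiking LPL rule. The membrane is held at clamp_voltage; pre
// spikes arrive at k/rho, the post spike of pair k is injected at
// k/rho + delta_t (delta_t > 0: causal pre-before-post). No weight bounds so
// LTD is measurable; no axonal delay (spike times are the protocol's own).
// [[Rcpp::export]]
List cpp_pairing_protocol(double delta_t, double rho, int n_pairings,
                          double w_init, double eta, List lpl,
                          double clamp_voltage, double theta_rest,
                          double sbar_init, double sigma2_init,
                          bool evolve_moments, double dt,
                          bool pre_spikes, bool post_spikes) {
  const double lambda   = as<double>(lpl["lambda"]);
  const double xi       = as<double>(lpl["xi"]);
  const double delta_tt = as<double>(lpl["delta"]);
  const double beta     = as<double>(lpl["beta"]);
  const double pred_delay = as<double>(lpl["pred_delay"]);
  const bool   pred_on  = as<bool>(lpl["pred_on"]);
  const double tau_mean = as<double>(lpl["tau_mean"]);
  const double tau_var  = as<double>(lpl["tau_var"]);
  const double tau_rate = as<double>(lpl["tau_rate"]);
  const double tau_a_r  = as<double>(lpl["tau_alpha_rise"]);
  const double tau_a_f  = as<double>(lpl["tau_alpha_fall"]);
  const double tau_e_r  = as<double>(lpl["tau_eps_rise"]);
  const double tau_e_f  = as<double>(lpl["tau_eps_fall"]);

  const double t0 = 0.1;                 // settle time before first pairing
  const double duration = t0 + n_pairings / rho + 0.3;
  const long n_steps = (long)std::llround(duration / dt);
  const int pred_steps = std::max(1, (int)std::lround(pred_delay / dt));

  // forced spike step indices
  std::vector<long> pre_steps(n_pairings), post_steps(n_pairings);
  for (int k = 0; k < n_pairings; ++k) {
    double t_pre = t0 + k / rho;
    pre_steps[k] = (long)std::llround(t_pre / dt);
    post_steps[k] = (long)std::llround((t_pre + delta_t) / dt);
  }

  double w = w_init;
  double u1 = 0.0, u2 = 0.0;             // epsilon trace of the pre spike train
  double el1 = 0.0, el2 = 0.0;           // alpha-filtered eligibility
  double err1 = 0.0, err2 = 0.0;         // alpha-filtered error
  double srate = 0.0, sbar = sbar_init, sigma2 = sigma2_init;
  std::vector<unsigned char> pring(pred_steps, 0);
  int ppos = 0;
  const double fprime = beta / std::pow(1.0 + beta * std::fabs(clamp_voltage - theta_rest), 2.0);

  size_t ipre = 0, ipost = 0;
  for (long s = 0; s < n_steps; ++s) {
    bool pre_spk = pre_spikes && (ipre < pre_steps.size() && pre_steps[ipre] == s);
    bool post_spk = post_spikes && (ipost < post_steps.size() && post_steps[ipost] == s);
    if (!pre_spikes && ipre < pre_steps.size() && pre_steps[ipre] == s) ++ipre;
    if (!post_spikes && ipost < post_steps.size() && post_steps[ipost] == s) ++ipost;
    if (pre_spk) { ++ipre; u1 += 1.0 / tau_e_r; w += eta * delta_tt; }
    if (post_spk) { ++ipost; srate += 1.0 / tau_rate; }

    double coef = lambda / (sigma2 + xi);
    double delta_w_err = 0.0;
    if (post_spk) delta_w_err += (pred_on ? -1.0 : 0.0) + coef;
    if (pring[ppos] & 1) delta_w_err += (pred_on ? 1.0 : 0.0);
    err1 += dt / tau_a_r * (-err1 - coef * sbar) + delta_w_err / tau_a_r;
    err2 += dt / tau_a_f * (err1 - err2);
    pring[ppos] = post_spk ? 1 : 0;
    ppos = (ppos + 1) % pred_steps;

    if (evolve_moments) {
      double dev = srate - sbar;
      sbar += dt / tau_mean * dev;
      sigma2 += dt / tau_var * (dev * dev - sigma2);
    }
    srate -= dt / tau_rate * srate;

    u1 -= dt / tau_e_r * u1;
    u2 += dt / tau_e_f * (u1 - u2);
    el1 += dt / tau_a_r * (-el1 + u2 * fprime);
    el2 += dt / tau_a_f * (el1 - el2);
    w += eta * el2 * err2 * dt;
  }

  return List::create(_["w_final"] = w,
                      _["rel_change"] = (w - w_init) / w_init,
                      _["sbar_final"] = sbar, _["sigma2_final"] = sigma2);
}
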