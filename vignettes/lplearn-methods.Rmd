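---
title: "Latent predictive learning: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent predictive learning: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`lplearn` simulates *latent predictive learning* (LPL), a local synaptic
plasticity rule that combines three forces on a neuron's output $z$:

* a **predictive** force that pulls the present response toward the
  (stop-gradient) response to the previous input,
  $\mathcal{L}_\mathrm{pred} = \frac{1}{2MB}\sum_b \lVert z^b(t) -
  \mathrm{SG}(z^b(t-\Delta t))\rVert^2$;
* a **Hebbian** force that maximises response variance,
  $\mathcal{L}_\mathrm{Hebb} = \frac{1}{M}\sum_i -\log(\sigma_i^2 +
  \epsilon)$, preventing the representational collapse that pure slowness
  objectives suffer;
* a **decorrelation** force on the off-diagonal structure of the batch
  covariance between units of the same layer, preventing dimensional
  collapse.

The weight update is the exact negative gradient of
$\mathcal{L}_\mathrm{pred} + \lambda_1 \mathcal{L}_\mathrm{Hebb} +
\lambda_2 \mathcal{L}_\mathrm{decorr}$ plus weight decay, with no gradient
through the previous activity, the mean estimate, or layer boundaries.
Rearranged, the rule is a BCM-style threshold rule whose sliding threshold
$\Theta = \bar z + (\sigma_z^2/\lambda)\,\mathrm{d}z/\mathrm{d}t$ moves
with the rate of change of the output and whose gain is inversely
modulated by the running output variance — a metaplasticity mechanism.
`lpl_update_single()` exposes both forms; they are algebraically identical
and tested as such.

The unit tests verify the closed-form update against central-difference
numerical gradients of the objective (relative error below $10^{-5}$)
under the stop-gradient conventions.

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `eta` | 0.05 (single neuron), 0.005 (stack) | — | SGD step; the stack value is the largest that trains all three layers stably |
| `lambda1` | 1 | — | Hebbian strength, fixed at 1 throughout the reference simulations |
| `lambda2` | 50 (stack) | — | decorrelation strength; see "Numerical choices" |
| `eta_w` | 0.01 (stack) | — | weight decay |
| `epsilon` | 1e-6 (single neuron), 1e-3 (stack) | — | variance floor; see "Numerical choices" |
| `delta_t` | 1 step | — | prediction horizon; constants of the finite-difference temporal derivative are absorbed into `eta` |

Spiking-rule constants (`spiking_lpl_params()`): learning rate $\eta =
10^{-2}$ (induction protocols use $5\times10^{-3}$), variance floor $\xi =
10^{-3}$, transmitter-triggered term $\delta = 10^{-5}$ per presynaptic
spike, surrogate steepness $\beta = 1\,\mathrm{mV}^{-1}$, prediction
horizon 20 ms, slow-moment time constants $\tau^\mathrm{mean} = 600$ s and
$\tau^\mathrm{var} = 20$ s, error/eligibility kernel 2/10 ms, PSP kernel
5/20 ms. The LIF neuron uses $\tau^\mathrm{mem} = 20$ ms, AMPA 5 ms,
threshold jump 100 mV with rest $-50$ mV, axonal delay 0.8 ms, step
0.1 ms.

# What the generators emulate — and what they do not

* **Two-cluster 2D sequences** (`gen_cluster_pairs()`): two Gaussian
  clusters at $x = \pm 1$, $\sigma_x = 0.1$; consecutive points share a
  cluster except for a fixed fraction of crossover pairs. Cluster
  identity is the temporally contiguous feature; $\sigma_y$ scales the
  unpredictable direction. A linear neuron and seconds of CPU reproduce
  the qualitative dichotomy between predictive and purely Hebbian
  learning; nothing about real sensory statistics is implied.
* **Slow Fourier signals** (`gen_slow_signal()`): $K = 20$ harmonics with
  coefficients $\theta_k/\alpha^k$, $\alpha = 1.1$, periods 3 s and
  $3 + 1/13$ s, centred on 5 Hz, unit variance, clipped at 0.1 Hz.
  The printed basis gives every harmonic the same frequency (the index
  appears only in the coefficient); we use the standard reading
  $\sin(2\pi k t/T + \phi_k)$. $K$ is not stated; 20 harmonics put >99%
  of the variance below ~7 Hz.
* **Poisson rasters** (`gen_poisson_raster()`): per-0.1 ms Bernoulli
  thinning, all neurons of a population share the instantaneous rate.
  Mean-rate calibration (5 Hz ± 2%) and ISI coefficient of variation ≈ 1
  are tested.
* **Latent-factor glyph videos** (`gen_latent_video()`): 17-frame clips;
  shape fixed within a clip, one of scale/hue/orientation performs an
  adjacent-biased walk; hue levels permuted once per run so pixel
  similarity does not encode hue adjacency. The glyphs (disk, square,
  triangle, cross) replace rendered 3D scenes; the *sequence statistics*
  (clip length, single varying factor, adjacency bias, occasional object
  switches at clip boundaries) are what the learning rule consumes, and
  only those are matched. A green test on this generator establishes that
  the rule extracts temporally contiguous structure from it — not
  performance on natural images.

# Numerical choices

* **Variance floor.** With $\epsilon = 10^{-6}$ a stack unit whose batch
  variance collapses receives an enormous Hebbian gradient
  ($\propto 1/(\sigma^2+\epsilon)$), destabilises its layer and dies
  (zero variance, zero rescue gradient — the smooth analogue of a dead
  rectifier). The stack default is $\epsilon = 10^{-3}$; the single
  neuron keeps the stated $10^{-6}$.
* **Decorrelation strength.** The printed loss is normalised by
  $(M^2-M)$, so its gradient per unit shrinks quadratically with layer
  width; $\lambda_2 = 50$ balances it against the Hebbian term for layers
  of width 32–128 with standardised inputs. Much larger values kill
  units; much smaller ones fail to spread variance across units.
* **Input standardisation between layers.** Hidden layers receive
  batch-standardised (mean/sd, stop-gradient) inputs, the
  batch-normalisation analogue that this family of networks customarily
  relies on. Without it the deep layers of a positive-activation network
  are dominated by the common-mode component and either fail to
  decorrelate or die at larger $\lambda_2$ (we observed both). Note the
  consequence, verified in our runs: downstream standardisation rescales
  a collapsing signal, so the *activity* collapse of the Hebbian-off
  ablation is measured on each layer's own outputs, pre-standardisation.
* **Activation.** The stack default is a shifted softplus
  ($\log(1+e^a) - \log 2$), monotone and smooth with $f(0)=0$, so a
  collapsed (zero-weight) unit is silent rather than pinned at
  $\log 2$. Linear and plain softplus are available; the single-neuron
  task is linear as stated.
* **Paired-view jitter.** `video_stream()` can add contrast/brightness
  jitter to each view (the colour-jitter analogue). At desk scale we
  found any such additive jitter *reduces* the trained representation's
  participation ratio (it adds unpredictable variance everywhere, which
  the predictive term answers by shrinking all features); the default
  stream is therefore the raw consecutive-frame pairing.
* **Protocol moments.** The STDP induction protocol freezes
  $\bar S(0), \sigma^2(0)$ by default. Their slow dynamics justify
  treating them as protocol parameters, and measured behaviour forces
  it: when $\sigma^2$ evolves, its input — the squared deviation of the
  clamped neuron's own forced firing — lifts it from 0.1 to ~4.6 within
  one protocol, and every window collapses onto the anti-Hebbian
  profile. The window sweep defaults to $\bar S(0) = \rho$ (the
  self-consistent adapted state); the frequency sweep uses the stated
  20 Hz.
* **Spiking moment estimator.** The variance dynamics square the
  deviation of the postsynaptic spike train from its slow mean; the
  square of a Dirac delta is undefined, so the implementation feeds the
  moment integrators with an auxiliary exponentially filtered rate
  estimate (`tau_rate`). Its value sets the operating scale of
  $\sigma^2$ and thereby the Hebbian gain; the default (2 s) makes
  $\sigma^2$ track rate modulations on the timescale of the slow input
  signals.
* **Desk-scale spiking runs.** The reference network runs 28 simulated
  hours; desk-scale experiments run minutes. Five scalings compensate,
  all frozen in `snn_experiment()` and documented here: the network
  learning rate is raised to 0.1–0.3 (protocols keep the stated
  $5\times10^{-3}$ and the full-size configuration the stated $10^{-2}$);
  the slow-moment timescales are compressed in proportion
  ($\tau^\mathrm{mean}$ 600 → 60 s, $\tau^\mathrm{var}$ 20 → 10 s), since
  the metaplastic feedback loop must close within the run; runs begin
  with a burn-in during which input plasticity is frozen while
  inhibitory plasticity and the slow moments settle (a long run reaches
  this operating point on its own); the slow moments are initialised
  self-consistently at the homeostatic target
  ($\bar S(0) = \kappa = 10$ Hz); and input weights keep a floor
  (`w_min = 0.1`) because a silenced desk-scale network cannot revive —
  the transmitter-triggered term $\delta = 10^{-5}$ restores weights on
  the reference's hour timescale, not in minutes. Initial
  I-to-E / I-to-I weights (0.3 / 1.5) were chosen so the settled network
  avoids strong synchrony: synchronous bursting inflates the variance
  estimate and silences the Hebbian term. Without these choices the
  startup transient inflates $\sigma^2$ for the entire run and the
  predictive term alone drags all input weights down.
* **Eligibility sub-grid.** The per-synapse double-exponential
  eligibility filters advance on a 1 ms sub-grid (neuron dynamics at
  0.1 ms); the kernels are 2–20 ms so the extra Euler error is small,
  and the sub-grid can be set to `dt` exactly for small tests.
* **Inhibitory STDP sign.** The printed pre-spike term
  $(x_i + 2\kappa\tau)$ is potentiation-only and admits no rate fixed
  point; we implement the cited model's convention $(x_i - 2\kappa\tau)$,
  whose drift vanishes at postsynaptic rate $\kappa$, and keep the
  printed literal form behind `literal_printed = TRUE` (its
  monotone-potentiation behaviour is itself under test).
* **Unspecified circuit constants.** Reversal potentials
  ($-70/0/-80$ mV), $\tau^\mathrm{nmda} = 100$ ms,
  $\tau^\mathrm{gaba} = 10$ ms, $\tau^\mathrm{thr} = 5$ ms, initial
  weights and pathway probabilities come from unavailable supplementary
  tables; defaults were chosen once so that the uninhibited reduced
  network fires in the tens of Hz (clearly needing inhibition) and the
  homeostatic network settles near $\kappa$; they are all
  config-overridable and frozen since.

# Known limitations

* Desk-scale networks are three dense layers on 32×32 glyphs; depth
  effects that emerge over many convolutional stages (the growth of
  readout accuracy with depth, the large readout gap between full LPL
  and its predictive-off ablation) are weak here. The ablation
  signatures that survive desk scale — dimensional collapse without
  decorrelation, representational collapse without the Hebbian term,
  dimensionality above 3 with the full rule — are the tested claims.
* The spiking experiments use a reduced circuit (200 inputs, 50 E, 12 I)
  for minutes of simulated time; weight selectivity magnitudes are far
  from the converged reference values and only their sign structure is
  asserted.
* The STDP window amplitude is not calibrated to any biological dataset;
  only sign structure, suppression and crossovers are claims. The window
  amplitude is *not* monotone across $\sigma^2(0) \in \{0.1, 1, 100\}$:
  the predictive term's amplitude is variance-independent, so near the
  point where Hebbian and predictive per-spike contributions cancel
  ($\sigma^2 \approx \lambda/1 - \xi$ with $\bar S(0) = \rho$) the window
  is smaller than the purely anti-Hebbian one.

# Reproducing the headline checks

```r
library(lplearn)

# selectivity crossover (Hebbian rules switch at sigma_y = 1; LPL does not)
sweep <- selectivity_sweep(seq(0.25, 2, 0.25), c("lpl", "pred_off", "oja"))
selectivity_crossover(sweep, "oja")

# dimensional collapse without decorrelation
video <- gen_latent_video(latent_video_config(n_frames = 3400, seed = 1))
stack <- layer_stack(c(1024, 128, 64, 32))
fit <- train_network(stack, video_stream(video, 128), 1000, "decorr_off")

# inhibitory rate fixed point
inputs <- make_snn_inputs(40, 300, seed = 1)
net <- build_network(network_topology(200, 50, 12), seed = 2)
res <- run_snn(net, inputs$raster, 300, lpl = spiking_lpl_params(on = FALSE))

# STDP window metaplasticity
stdp_window_sweep(seq(-50, 50, 5), sigma2_init = 0.1)
```

Each of these is executed, with tolerances, by `tests/testthat/` and
`scripts/acceptance.R`; the vignette intentionally states no numbers that
those runs do not themselves produce.
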