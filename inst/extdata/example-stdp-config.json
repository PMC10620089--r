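{
  "experiment": "stdp",
  "seed": 1,
  "delta_t_grid": [-50, -40, -30, -20, -10, -5, 5, 10, 20, 30, 40, 50],
  "sigma2_init": 0.1,
  "sbar_init": 10,
  "rho": 10
}
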