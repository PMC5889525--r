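{
  "n_patients": 10000,
  "site": "lung",
  "p_ep_base": 0.44,
  "confounding_coefs": {"age": 0.4, "imd": 0.25, "comorb": 0.15},
  "weibull_shape": 0.9,
  "weibull_scale_ep": 5.53,
  "aft_route_factor": 2.38,
  "covariate_coefs_survival": {"age": -0.25, "imd": -0.05, "comorb": -0.1},
  "cost_params": {
    "baseline_mean": 350, "diagnosis_spike_mean": 1600,
    "terminal_spike_mean": 2000, "predx_mean_ep": 320, "predx_mean_gp": 275.5,
    "route_intensity_ratio": 1.2, "gamma_shape": 0.6, "p_zero": 0.35
  },
  "entry_window_months": 36,
  "admin_cutoff_month": 48,
  "seed": 2009
}
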