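{
  "n_patients": 10000,
  "site": "breast",
  "p_ep_base": 0.067,
  "confounding_coefs": {"age": 0.4, "imd": 0.25, "comorb": 0.15},
  "weibull_shape": 0.9,
  "weibull_scale_ep": 20.5,
  "aft_route_factor": 14.3,
  "covariate_coefs_survival": {"age": -0.25, "imd": -0.05, "comorb": -0.1},
  "cost_params": {
    "baseline_mean": 200, "diagnosis_spike_mean": 1400,
    "terminal_spike_mean": 1600, "predx_mean_ep": 200, "predx_mean_gp": 158.6,
    "route_intensity_ratio": 1.4, "gamma_shape": 0.6, "p_zero": 0.35
  },
  "entry_window_months": 36,
  "admin_cutoff_month": 72,
  "seed": 2007
}
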