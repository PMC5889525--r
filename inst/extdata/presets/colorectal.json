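{
  "n_patients": 10000,
  "site": "colorectal",
  "p_ep_base": 0.315,
  "confounding_coefs": {"age": 0.4, "imd": 0.25, "comorb": 0.15},
  "weibull_shape": 0.8,
  "weibull_scale_ep": 18.8,
  "aft_route_factor": 3.82,
  "covariate_coefs_survival": {"age": -0.25, "imd": -0.05, "comorb": -0.1},
  "cost_params": {
    "baseline_mean": 300, "diagnosis_spike_mean": 1500,
    "terminal_spike_mean": 1500, "predx_mean_ep": 290, "predx_mean_gp": 244.5,
    "route_intensity_ratio": 1.3, "gamma_shape": 0.6, "p_zero": 0.35
  },
  "entry_window_months": 36,
  "admin_cutoff_month": 72,
  "seed": 2006
}
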