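{
  "n_patients": 10000,
  "site": "prostate",
  "p_ep_base": 0.108,
  "confounding_coefs": {
    "age": 0.4,
    "imd": 0.25,
    "comorb": 0.15
  },
  "weibull_shape": 0.9,
  "weibull_scale_ep": 24.6,
  "aft_route_factor": 13.0,
  "covariate_coefs_survival": {
    "age": -0.25,
    "imd": -0.05,
    "comorb": -0.1
  },
  "cost_params": {
    "baseline_mean": 200,
    "diagnosis_spike_mean": 1200,
    "terminal_spike_mean": 1000,
    "predx_mean_ep": 260,
    "predx_mean_gp": 186.1,
    "route_intensity_ratio": 1.8,
    "gamma_shape": 0.6,
    "p_zero": 0.35
  },
  "entry_window_months": 36,
  "admin_cutoff_month": 72,
  "seed": 2008
}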