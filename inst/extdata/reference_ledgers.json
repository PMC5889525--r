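{
  "comment": "Published per-site referral-economics and ledger components of the English cancer-registry rerouting analysis (2010 GBP prices; lung followed 36 months, other sites 60), plus the published policy scale-up rows benchmarking commissioning groups against their best-performing quintile.",
  "sites": {
    "colorectal": {
      "conversion_rate": 0.043, "cost_per_test": 420,
      "a": 9242, "b": -546, "c1": 479, "d1": -1734, "total_1yr": 7442,
      "C": 1128, "D": -1012, "total_h": 8812,
      "delta_surv": 0.359, "cost_per_survivor": 24546,
      "yls": 1.43, "cost_per_yls": 6162, "horizon": 60
    },
    "breast": {
      "conversion_rate": 0.078, "cost_per_test": 158,
      "a": 1883, "b": -497, "c1": 128, "d1": -1546, "total_1yr": -32,
      "C": 712, "D": -628, "total_h": 1469,
      "delta_surv": 0.512, "cost_per_survivor": 2870,
      "yls": 1.54, "cost_per_yls": 954, "horizon": 60
    },
    "prostate": {
      "conversion_rate": 0.153, "cost_per_test": 157,
      "a": 874, "b": -887, "c1": -128, "d1": -2565, "total_1yr": -2706,
      "C": 616, "D": -1582, "total_h": -979,
      "delta_surv": 0.408, "cost_per_survivor": -2399,
      "yls": 1.24, "cost_per_yls": -789, "horizon": 60
    },
    "lung": {
      "conversion_rate": 0.186, "cost_per_test": 127,
      "a": 559, "b": -534, "c1": 669, "d1": -952, "total_1yr": -258,
      "C": 907, "D": -577, "total_h": 356,
      "delta_surv": 0.149, "cost_per_survivor": 2388,
      "yls": 0.59, "cost_per_yls": 603, "horizon": 36
    }
  },
  "policy": {
    "site": ["colorectal", "breast", "prostate", "lung"],
    "rerouted": [1303, 577, 964, 1714],
    "non_converted": [29977, 7436, 6320, 9236],
    "share_of_annual_diagnoses": [0.0316, 0.0104, 0.0207, 0.0369],
    "total_cost_1yr": [9696503, -18260, -2608444, -441712],
    "total_cost_h": [11481948, 847750, -943434, 609938],
    "survivors": [468, 295, 393, 255],
    "yls_total": [1863, 889, 1195, 1011]
  }
}
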