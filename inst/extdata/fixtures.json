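{
  "bistable": {
    "params": {
      "k1p": 3.33016340315944,
      "k2p": 60.6909076995957,
      "k3p": 1.80544816150355,
      "k4p": 4.68001642088779,
      "k1m": 4.10579508452457,
      "k2m": 0.170820510382888,
      "k3m": 6.00337479050169,
      "k4m": 0.147398240233144,
      "kFn": 0.047954581083711,
      "kFp": 12.8185126141136,
      "g": 6.79082816119971,
      "K": 40.8784396412664
    },
    "validation": {
      "cba_class_u0": "bistable",
      "n_steady_cba": 3,
      "n_steady_newton": 3,
      "r60": 1.02118331582638,
      "r600": 1.02106127082863,
      "t_switch_min": "NA",
      "t_mono_min": "NA",
      "u_snb": 0.000621741797362433,
      "plateau_ratio": "NA"
    }
  },
  "quasi_bistable": {
    "params": {
      "k1p": 0.0921679009230274,
      "k2p": 20.6786074381491,
      "k3p": 0.519376321896621,
      "k4p": 0.837230724879476,
      "k1m": 0.900975291082749,
      "k2m": 0.590978659024996,
      "k3m": 0.0143018149928521,
      "k4m": 0.483973920249765,
      "kFn": 51.1453272236601,
      "kFp": 5.14902209404325,
      "g": 7.0693841406073,
      "K": 12.4750033889763
    },
    "validation": {
      "cba_class_u0": "monostable",
      "n_steady_cba": 1,
      "n_steady_newton": 1,
      "r60": 1.4340112789987,
      "r600": 7.51514843827843e-07,
      "t_switch_min": 202.574494484759,
      "t_mono_min": 69.6309571479149,
      "u_snb": [0.00571774582094637, 0.114602257616445],
      "plateau_ratio": 0.0012514773842856
    }
  },
  "monostable": {
    "params": {
      "k1p": 0.0152190105422172,
      "k2p": 0.71713031065973,
      "k3p": 0.0121975663626636,
      "k4p": 3.17832450980606,
      "k1m": 23.7961619152964,
      "k2m": 54.331449774789,
      "k3m": 64.0127113987528,
      "k4m": 0.436387336488129,
      "kFn": 80.1768167986809,
      "kFp": 0.145962408365298,
      "g": 3.17535757172478,
      "K": 3.88071896629737
    },
    "validation": {
      "cba_class_u0": "monostable",
      "n_steady_cba": 1,
      "n_steady_newton": 1,
      "r60": 2.62637323504566e-07,
      "r600": 2.02412990204926e-13,
      "t_switch_min": "NA",
      "t_mono_min": "NA",
      "u_snb": [],
      "plateau_ratio": "NA"
    }
  },
  "search": {
    "seed": 20260923,
    "n_search": 20000,
    "n_used": 9765
  },
  "note": "synthetic fixtures discovered by seeded randomized search; not experimental estimates"
}
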