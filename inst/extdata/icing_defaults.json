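{
  "version": "1.0",
  "source": "literature defaults for the adult ICING glucose-insulin model",
  "parameters": {
    "p_G": 0.006,
    "alpha_G": 0.01538462,
    "alpha_I": 0.0017,
    "n_K": 0.0542,
    "n_L": 0.1578,
    "n_I": 0.006,
    "n_C": 0.006,
    "x_L": 0.67,
    "V_G": 13.3,
    "V_I": 4.0,
    "EGP": 1.16,
    "CNS": 0.3,
    "u_en_basal": 16.7,
    "u_en_max": 266.7,
    "u_en_slope": 14.9,
    "u_en_intercept": -49.9,
    "printed_nk_sign": false
  }
}
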