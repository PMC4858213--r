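{
  "schema_version": "1",
  "model": "isn",
  "params": {
    "rho": 0.03,
    "Ie_half": 44.68,
    "S_half": 0.008,
    "a2": 0,
    "a3": 1.2,
    "a4": 0.6,
    "aP": 0,
    "a6": 5,
    "a6p": 0.2,
    "a7": 0,
    "a8": 1,
    "a9": 2.5,
    "a10": 2.5,
    "a10mu": 0,
    "a11": 0,
    "a12": 3e-05,
    "a13d": 0.0846327672262193,
    "a15e": 0.0846327672262193,
    "a17g": 0.4,
    "a17d": 0.9,
    "a19g": 0.4,
    "a19e": 0.9,
    "a_theta_e": 0.5,
    "a_eta_d": 0.5,
    "mu_ratio": 0.005,
    "a21": 2,
    "a23": 2.5,
    "a23p": 0,
    "a24": 2.5,
    "a26": 3,
    "a26mu": 0.01,
    "a27": 3,
    "a28": 0.22,
    "a29": 12.120212737651,
    "a30": 14,
    "a_as160": 0.5,
    "gsk3b_substrate": "aktT"
  }
}
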