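{
  "schema_version": "1",
  "model": "isn",
  "params": {
    "rho": 0.03,
    "Ie_half": 9.69,
    "S_half": 0.035,
    "a2": 0,
    "a3": 1,
    "a4": 0.8,
    "aP": 0,
    "a6": 6,
    "a6p": 0.3,
    "a7": 0,
    "a8": 1,
    "a9": 3,
    "a10": 3,
    "a10mu": 0,
    "a11": 30,
    "a12": 3e-05,
    "a13d": 1.64596523216857,
    "a15e": 1.64596523216857,
    "a17g": 1.09731015477905,
    "a17d": 2.60611161760023,
    "a19g": 1.09731015477905,
    "a19e": 2.60611161760023,
    "a_theta_e": 0.5,
    "a_eta_d": 0.5,
    "mu_ratio": 0.005,
    "a21": 3,
    "a23": 3,
    "a23p": 1.5,
    "a24": 3,
    "a26": 3,
    "a26mu": 0.01,
    "a27": 3,
    "a28": 0.020284,
    "a29": 0.045384,
    "a30": 0.053393,
    "a_as160": 0.5,
    "gsk3b_substrate": "aktT"
  }
}
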