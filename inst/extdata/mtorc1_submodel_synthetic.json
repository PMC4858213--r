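{
  "schema_version": "1",
  "model": "mtorc1_submodel",
  "params": {
    "K_TSC": 65.95,
    "K_Rheb": 6.48,
    "K_mTORC1": 0.0072,
    "K_PRAS": 16.72,
    "phi": -0.67,
    "K_mTOR": 0.0123722771640329,
    "K_mTOR_mu": 0.0001
  }
}
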