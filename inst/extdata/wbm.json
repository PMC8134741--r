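{
  "model": "wbm",
  "params": {
    "c": 1,
    "g_l": 0.1,
    "g_Na": 35,
    "g_K": 9,
    "E_l": -65,
    "E_Na": 55,
    "E_K": -90,
    "phi": 5
  }
}
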