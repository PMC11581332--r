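{
  "version": "toy-synthetic-3L (not a published tariff)",
  "constant": 1,
  "u_min": -0.53
}
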