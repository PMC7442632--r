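{
  "treatment": "bonobo",
  "n_days": 5,
  "nest_rate": 0.3
}
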