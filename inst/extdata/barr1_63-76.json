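{
  "name": "barr1",
  "sequence": "YGREDLDVLGLTFR",
  "start_number": 63,
  "n_term_mod": "acetyl",
  "c_term_mod": "amide"
}
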