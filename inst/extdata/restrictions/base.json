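{
  "share": [
    {"param": "dA", "conditions": "all"},
    {"param": "dP", "conditions": ["sim_morphed", "sim_nonmorphed"]},
    {"param": "dP", "conditions": ["seq_morphed", "seq_nonmorphed"]},
    {"param": "g",  "conditions": ["sim_morphed", "sim_nonmorphed"]},
    {"param": "g",  "conditions": ["seq_morphed", "seq_nonmorphed"]}
  ]
}
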