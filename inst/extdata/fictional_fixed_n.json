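{
  "comment": "fictional three-group study with the total sample size fixed at 300",
  "groups": [
    {"label": "group1", "mean": 0.2, "variance": 1.0},
    {"label": "group2", "mean": 0.4, "variance": 1.0},
    {"label": "group3", "mean": 0.6, "variance": 1.0}
  ],
  "total_n": 300
}
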