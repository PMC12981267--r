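{
  "comment": "fictional three-group study: equal unit variances, equal costs, small equally spaced effects",
  "groups": [
    {"label": "group1", "mean": 0.2, "variance": 1.0, "cost": 100},
    {"label": "group2", "mean": 0.4, "variance": 1.0, "cost": 100},
    {"label": "group3", "mean": 0.6, "variance": 1.0, "cost": 100}
  ],
  "budget": 30000
}
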