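{
  "comment": "multidisciplinary pain management study under the budget actually spent",
  "groups": [
    {"label": "NT",      "mean": 17.3, "variance": 61.6225,  "cost": 2328.58},
    {"label": "CBT+PCT", "mean": 23.9, "variance": 397.2049, "cost": 2695.12},
    {"label": "PCT",     "mean": 45.9, "variance": 528.5401, "cost": 6281.18}
  ],
  "budget": 101766.22
}
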