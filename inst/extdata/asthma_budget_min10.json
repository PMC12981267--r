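{
  "comment": "asthma study under the budget actually spent, minimum group sizes of 10",
  "groups": [
    {"label": "CL", "mean": 0.13, "variance": 0.1156, "cost": 82.94,  "min_n": 10},
    {"label": "CH", "mean": 0.38, "variance": 0.5929, "cost": 242.44, "min_n": 10},
    {"label": "AH", "mean": 0.42, "variance": 0.5184, "cost": 267.96, "min_n": 10},
    {"label": "AL", "mean": 1.23, "variance": 0.6889, "cost": 784.94, "min_n": 10}
  ],
  "budget": 21692.00
}
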