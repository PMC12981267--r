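{
  "comment": "psychological status and asthma outcomes, emergency service use; 2x2 factorial, total sample size fixed at 73",
  "groups": [
    {"label": "CL", "mean": 0.13, "variance": 0.1156},
    {"label": "CH", "mean": 0.38, "variance": 0.5929},
    {"label": "AH", "mean": 0.42, "variance": 0.5184},
    {"label": "AL", "mean": 1.23, "variance": 0.6889}
  ],
  "total_n": 73
}
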