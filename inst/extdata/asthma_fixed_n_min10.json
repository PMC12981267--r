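{
  "comment": "asthma study, total sample size 73, minimum group sizes of 10",
  "groups": [
    {"label": "CL", "mean": 0.13, "variance": 0.1156, "min_n": 10},
    {"label": "CH", "mean": 0.38, "variance": 0.5929, "min_n": 10},
    {"label": "AH", "mean": 0.42, "variance": 0.5184, "min_n": 10},
    {"label": "AL", "mean": 1.23, "variance": 0.6889, "min_n": 10}
  ],
  "total_n": 73
}
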