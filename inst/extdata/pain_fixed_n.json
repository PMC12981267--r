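{
  "comment": "multidisciplinary pain management study, posttreatment health care visits; total sample size fixed at 31",
  "groups": [
    {"label": "NT",      "mean": 17.3, "variance": 61.6225},
    {"label": "CBT+PCT", "mean": 23.9, "variance": 397.2049},
    {"label": "PCT",     "mean": 45.9, "variance": 528.5401}
  ],
  "total_n": 31
}
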