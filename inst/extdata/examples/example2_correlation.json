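{
  "description": "Planned correlation between occipital-cortex receptor binding (ICC 0.8 in healthy controls) and a self-report scale (reliability 0.7), powered for a maximum realistic 30% explained variance.",
  "trt": {"mean": 1.6, "sd": 0.11, "icc": 0.8, "n": 12, "k": 2},
  "new": {"sd_ratio": 1},
  "tau": 1,
  "power": {
    "rel_other": 0.7,
    "max_r2_biological": 0.30,
    "alpha": 0.05,
    "power": 0.8,
    "sides": "two"
  }
}
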