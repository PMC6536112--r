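{
  "description": "Ratio-based quantification with poor reliability (ICC 0.5): the between-group separation (Cohen's d) needed for the combined 20+20 sample to reach lowest-acceptable (0.7), acceptable (0.8) and clinical (0.9) reliability, assuming equal within-group SDs equal to the test-retest SD.",
  "trt": {"mean": 1.0, "sd": 1.0, "icc": 0.5, "n": 12, "k": 2},
  "new": {"sd_ratio": 1},
  "tau": 1,
  "required_d": {"targets": [0.7, 0.8, 0.9], "n1": 20, "n2": 20, "sd_ratio_2to1": 1},
  "overlap": {"d": 0.8}
}
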