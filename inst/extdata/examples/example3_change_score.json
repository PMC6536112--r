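{
  "description": "Pharmacological-displacement change score (percent change in binding): SD of test-retest differences 7.3, expected change-score SD 10 within groups, patients expected to release 2.5x more (means -12 vs -30, n 20+20). The change-score error SD is sqrt(2)*7.3 (two measurements contribute error); the SDD block uses the single-measurement convention sigma_e = 7.3/sqrt(2).",
  "trt": {"mean": -12, "sd": 10, "icc": -0.0658, "n": 20, "k": 2, "sem": 10.3237590053},
  "new": {
    "groups": [
      {"n": 20, "mean": -12, "sd": 10},
      {"n": 20, "mean": -30, "sd": 10}
    ]
  },
  "tau": 1,
  "sdd": {"sigma_e": 5.1618795027, "conf": 0.95, "n_group": 2},
  "effect": {"d_true": 1.8, "n1": 20, "n2": 20}
}
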