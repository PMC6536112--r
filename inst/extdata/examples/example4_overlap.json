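{
  "description": "Translocator-protein tracer distribution volume: very high between-subject variability (CV ~ 40%) gives high reliability (ICC ~ 0.9), but a conventionally large effect (d = 0.8) still corresponds to a >30% mean difference. Overlap descriptors put the d = 0.8 effect in perspective.",
  "trt": {"mean": 1.0, "sd": 0.4, "icc": 0.9, "n": 12, "k": 2},
  "new": {"sd_ratio": 1},
  "tau": 1,
  "overlap": {"d": 0.8}
}
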