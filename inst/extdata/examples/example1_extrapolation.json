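{
  "description": "Serotonin 1B receptor tracer, frontal cortex binding potential: low test-retest ICC in a homogeneous healthy sample, extrapolated to an applied ageing study whose sample SD was 3.2-fold larger.",
  "trt": {"mean": 1.6, "sd": 0.11, "icc": 0.32, "n": 12, "k": 2},
  "new": {"sd_ratio": 3.2},
  "tau": 1
}
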