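# Example run configuration: a small cohort under the default study
# conditions with a slightly tighter hormone distribution.
parameters:
  betaMean: 5
  betaSd: 0.5
  mutationsPerDivision: 2
  detectThreshold: 1.0e6
experiment:
  mode: cohort
  n: 100
seed: 42
recording: compressed
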