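# Example run configuration: theoretical ratios of the F6 heterozygous
# sibling cross of the single-transgene scheme.
#   loxcross enumerate --config f6_cross.yaml
cross:
  scheme: acos
  stage: F6
params:
  beta: 0.5
  completeness: 1.0
simulation:
  n_per_cross: 200
  seed: 1
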