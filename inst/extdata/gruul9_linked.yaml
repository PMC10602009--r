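# Example run configuration: the linked special case -- both transgenes on
# ChLG9 at 8.31 cM. Enumerate the F9 sibling cross or run the whole
# double-transgene procedure:
#   loxcross enumerate --config gruul9_linked.yaml
#   loxcross run-procedure --config gruul9_linked.yaml --n 2000 --seed 1
cross:
  scheme: agoc_acos
  stage: F9
  agoc_chromosome: ChLG9
  linkage_cM: 8.31
params:
  beta: 0.5
  completeness: 1.0
simulation:
  n_per_cross: 2000
  seed: 1
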