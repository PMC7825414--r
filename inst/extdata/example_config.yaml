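# Example experiment configuration for lumbarload::run_experiment().
# A small smoke-scale run: 2 participants x a reduced battery, idealized
# features, trunk vs trunk+insoles.
seed: 1
cohort:
  "n": 2
battery:
  masses: [0, 10, 23]
  repetitions: 1
features:
  provenance: idealized
  stride: 4
  rate: 100
target: extension
estimator:
  n_trees: 100
  learning_rate: 0.1
sweep:
  subsets:
    - [trunk]
    - [trunk, insole]
output:
  importance: true
  importance_subset: [trunk, insole]
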