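weighted_forest:
  num_trees:
  - 100
  - 200
  - 500
  max_depth:
  - 4
  - 8
  - 0
weighted_logistic:
  reg_strength:
  - 0.01
  - 0.1
  - 1.0
  - 10.0
balanced_forest:
  num_trees:
  - 100
  - 200
  - 500
  max_depth:
  - 4
  - 8
  - 0
undersampled_boost_ensemble:
  n_members:
  - 10
  - 50
  n_rounds:
  - 20
  - 50
  max_depth:
  - 1
  - 2
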