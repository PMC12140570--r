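# Synthetic reconstruction of the ten-option Gaussian task with two binary
# and two ternary contexts. Means span the published ~[8, 92] dollar range
# (sd 2), reproduce the ideal higher-relative-value choice rate of 0.969
# (31/32 non-tied transfer pairs congruent, a single incongruent pair) and
# contain one equal-EV transfer pair (the two 86-mean options, tied on
# relative rank). Edit freely: all analysis code is config-driven.
name: BP2023
currency: dollars
transfer_reps: 1
contexts:
- context_id: c1
  n_learning_trials: 15
  options:
  - {option_id: 1L, kind: gaussian, mean: 14.0, sd: 2.0}
  - {option_id: 1H, kind: gaussian, mean: 86.0, sd: 2.0}
- context_id: c2
  n_learning_trials: 15
  options:
  - {option_id: 2L, kind: gaussian, mean: 32.0, sd: 2.0}
  - {option_id: 2H, kind: gaussian, mean: 46.0, sd: 2.0}
- context_id: c3
  n_learning_trials: 15
  options:
  - {option_id: 3L, kind: gaussian, mean: 8.0, sd: 2.0}
  - {option_id: 3M, kind: gaussian, mean: 50.0, sd: 2.0}
  - {option_id: 3H, kind: gaussian, mean: 92.0, sd: 2.0}
- context_id: c4
  n_learning_trials: 15
  options:
  - {option_id: 4L, kind: gaussian, mean: 26.0, sd: 2.0}
  - {option_id: 4M, kind: gaussian, mean: 44.0, sd: 2.0}
  - {option_id: 4H, kind: gaussian, mean: 86.0, sd: 2.0}
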