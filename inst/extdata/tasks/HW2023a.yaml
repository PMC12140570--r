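# Eight Gaussian options (sd $1) in four binary contexts. Means follow the
# uniform $3 staircase 15..36, the unique even-spacing layout consistent with
# the published EVs of options 1H ($18), 2L ($21) and 4L ($33), the ~[12, 39]
# reward range, the ideal higher-relative-value choice rate of 0.625 and the
# six incongruent transfer pairs.
name: HW2023a
currency: dollars
transfer_reps: 1
contexts:
- context_id: c1
  n_learning_trials: 15
  options:
  - {option_id: 1L, kind: gaussian, mean: 15.0, sd: 1.0}
  - {option_id: 1H, kind: gaussian, mean: 18.0, sd: 1.0}
- context_id: c2
  n_learning_trials: 15
  options:
  - {option_id: 2L, kind: gaussian, mean: 21.0, sd: 1.0}
  - {option_id: 2H, kind: gaussian, mean: 24.0, sd: 1.0}
- context_id: c3
  n_learning_trials: 15
  options:
  - {option_id: 3L, kind: gaussian, mean: 27.0, sd: 1.0}
  - {option_id: 3H, kind: gaussian, mean: 30.0, sd: 1.0}
- context_id: c4
  n_learning_trials: 15
  options:
  - {option_id: 4L, kind: gaussian, mean: 33.0, sd: 1.0}
  - {option_id: 4H, kind: gaussian, mean: 36.0, sd: 1.0}
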