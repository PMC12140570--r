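# Synthetic reconstruction of the eight-option Bernoulli task with two loss
# contexts (outcomes -1/0 euros) and two gain contexts (outcomes 0/1 euros).
# Win probabilities are twelfths so that exact-frequency sampling is integral
# at 12 learning trials per context; the EV staircase reproduces the
# published reward range [-1, 1], the ideal higher-relative-value choice rate
# of 0.625 and six incongruent transfer pairs. Edit freely: all analysis code
# is config-driven.
name: B2018
currency: euros
transfer_reps: 1
contexts:
- context_id: c1
  n_learning_trials: 12
  options:
  - {option_id: 1L, kind: bernoulli, win_prob: 0.16666666666666666, hi_value: 0.0, lo_value: -1.0}
  - {option_id: 1H, kind: bernoulli, win_prob: 0.4166666666666667, hi_value: 0.0, lo_value: -1.0}
- context_id: c2
  n_learning_trials: 12
  options:
  - {option_id: 2L, kind: bernoulli, win_prob: 0.6666666666666666, hi_value: 0.0, lo_value: -1.0}
  - {option_id: 2H, kind: bernoulli, win_prob: 0.9166666666666666, hi_value: 0.0, lo_value: -1.0}
- context_id: c3
  n_learning_trials: 12
  options:
  - {option_id: 3L, kind: bernoulli, win_prob: 0.16666666666666666, hi_value: 1.0, lo_value: 0.0}
  - {option_id: 3H, kind: bernoulli, win_prob: 0.4166666666666667, hi_value: 1.0, lo_value: 0.0}
- context_id: c4
  n_learning_trials: 12
  options:
  - {option_id: 4L, kind: bernoulli, win_prob: 0.6666666666666666, hi_value: 1.0, lo_value: 0.0}
  - {option_id: 4H, kind: bernoulli, win_prob: 0.9166666666666666, hi_value: 1.0, lo_value: 0.0}
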