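# Synthetic reconstruction of the eight-option Bernoulli task with two-point
# dollar outcomes in [10, 44]. Contexts c1 and c2 align frequency and
# expected value; in c3 and c4 the frequent winner (the option whose draws
# beat its partner's on most trials) has the LOWER expected value, the
# frequency/EV conflict characteristic of this design. Win probabilities are
# multiples of 1/15 or exactly 1/3 so exact-frequency sampling is integral at
# 15 learning trials per context; the layout reproduces the published ideal
# higher-relative-value choice rate of 0.500. Edit freely: all analysis code
# is config-driven.
name: HW2023b
currency: dollars
transfer_reps: 1
contexts:
- context_id: c1
  n_learning_trials: 15
  options:
  - {option_id: 1L, kind: bernoulli, win_prob: 0.4, hi_value: 20.0, lo_value: 10.0}
  - {option_id: 1H, kind: bernoulli, win_prob: 0.6, hi_value: 22.0, lo_value: 12.0}
- context_id: c2
  n_learning_trials: 15
  options:
  - {option_id: 2L, kind: bernoulli, win_prob: 0.4, hi_value: 44.0, lo_value: 34.0}
  - {option_id: 2H, kind: bernoulli, win_prob: 0.6, hi_value: 44.0, lo_value: 39.0}
- context_id: c3
  n_learning_trials: 15
  options:
  - {option_id: 3L, kind: bernoulli, win_prob: 0.8, hi_value: 24.0, lo_value: 14.0}
  - {option_id: 3H, kind: bernoulli, win_prob: 0.3333333333333333, hi_value: 44.0, lo_value: 17.0}
- context_id: c4
  n_learning_trials: 15
  options:
  - {option_id: 4L, kind: bernoulli, win_prob: 0.8, hi_value: 32.0, lo_value: 22.0}
  - {option_id: 4H, kind: bernoulli, win_prob: 0.3333333333333333, hi_value: 44.0, lo_value: 29.0}
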