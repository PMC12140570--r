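# Four options in two binary contexts, Bernoulli 0/1 point rewards with
# win probabilities {0.1, 0.4} and {0.6, 0.9}; 60 learning trials, two
# transfer choices per option pair.
name: V2023
currency: points
transfer_reps: 2
contexts:
- context_id: c1
  n_learning_trials: 30
  options:
  - {option_id: 1L, kind: bernoulli, win_prob: 0.1, hi_value: 1.0, lo_value: 0.0}
  - {option_id: 1H, kind: bernoulli, win_prob: 0.4, hi_value: 1.0, lo_value: 0.0}
- context_id: c2
  n_learning_trials: 30
  options:
  - {option_id: 2L, kind: bernoulli, win_prob: 0.6, hi_value: 1.0, lo_value: 0.0}
  - {option_id: 2H, kind: bernoulli, win_prob: 0.9, hi_value: 1.0, lo_value: 0.0}
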