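# Independent straight-line reimplementation of the session likelihood,
# written directly from the model equations (subjective-value mixture,
# delta-rule update with confirmatory/disconfirmatory rates, softmax with
# first-position bias). Deliberately does not call any package internals so
# it can serve as an oracle for the compiled engine.
oracle_loglik <- function(trials, task, p) {
  ids <- task$options$option_id
  ll <- 0
  for (sid in unique(trials$session_id)) {
    s <- trials[trials$session_id == sid, ]
    s <- s[order(s$trial), ]
    Q <- setNames(rep(0.5, length(ids)), ids)
    rmin <- Inf; rmax <- -Inf
    for (i in seq_len(nrow(s))) {
      row <- s[i, ]
      opts <- stats::na.omit(c(row$option_1, row$option_2, row$option_3))
      if (is.na(row$choice) || !row$valid) next
      beta <- if (row$phase == "learning") p$beta_learn else p$beta_transfer
      u <- beta * Q[opts]
      u[1] <- u[1] + p$bias
      pr <- exp(u - max(u)); pr <- pr / sum(pr)
      ll <- ll + log(pr[[row$choice]])
      if (row$phase == "learning") {
        out <- c(row$outcome_1, row$outcome_2, row$outcome_3)[seq_along(opts)]
        rmin <- min(rmin, out); rmax <- max(rmax, out)
        tmin <- min(out); tmax <- max(out)
        for (k in seq_along(opts)) {
          xa <- if (rmax > rmin) (out[k] - rmin) / (rmax - rmin) else 0.5
          xr <- if (tmax > tmin) (out[k] - tmin) / (tmax - tmin) else 0.5
          v <- (1 - p$omega) * xa + p$omega * xr
          d <- v - Q[[opts[k]]]
          if (d != 0) {
            conf <- if (opts[k] == row$choice) d > 0 else d < 0
            a <- if (conf) p$alpha_con else p$alpha_dis
            Q[[opts[k]]] <- Q[[opts[k]]] + a * d
          }
        }
      }
    }
  }
  ll
}

# small configurable binary-context task for unit tests
toy_task <- function(p1 = 0.25, p2 = 0.75, n_learn = 12, reps = 1,
                     name = "toy") {
  load_task_spec(list(
    name = name, currency = "points", transfer_reps = reps,
    contexts = list(list(
      context_id = "c1", n_learning_trials = n_learn,
      options = list(
        list(option_id = "A", kind = "bernoulli", win_prob = p1,
             hi_value = 1, lo_value = 0),
        list(option_id = "B", kind = "bernoulli", win_prob = p2,
             hi_value = 1, lo_value = 0))))))
}
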