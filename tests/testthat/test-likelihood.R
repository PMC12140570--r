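test_that("encode_outcomes implements the absolute/relative mixture", {
  # pure absolute: running range [0, 40]
  e <- encode_outcomes(c(a = 20, b = 10), state = list(min = 0, max = 40), omega = 0)
  expect_equal(unname(e$values), c(0.5, 0.25))
  # pure relative: two-point trial range
  e <- encode_outcomes(c(a = 16, b = 14), omega = 1)
  expect_equal(unname(e$values), c(1, 0))
  # even mixture
  e <- encode_outcomes(c(a = 20, b = 10), state = list(min = 0, max = 40), omega = 0.5)
  expect_equal(unname(e$values[1]), 0.75)
  # degenerate ranges map to 0.5
  e <- encode_outcomes(c(a = 7, b = 7), omega = 0.3)
  expect_equal(unname(e$values), c(0.5, 0.5))
  expect_error(encode_outcomes(c(a = 1, b = 0), omega = 1.2), "omega")
  expect_error(encode_outcomes(c(a = 1), omega = 0), "complete feedback")
})

test_that("subjective values are convex combinations of the two normalizations", {
  set.seed(42)
  for (i in 1:50) {
    m <- sample(2:3, 1)
    out <- setNames(runif(m, -5, 5), letters[1:m])
    st <- list(min = min(out) - runif(1, 0, 3), max = max(out) + runif(1, 0, 3))
    w <- runif(1)
    ea <- encode_outcomes(out, st, omega = 0)$values
    er <- encode_outcomes(out, st, omega = 1)$values
    ew <- encode_outcomes(out, st, omega = w)$values
    expect_true(all(ew >= pmin(ea, er) - 1e-12 & ew <= pmax(ea, er) + 1e-12))
    expect_true(all(ew >= 0 & ew <= 1))
  }
})

test_that("feedback classification follows the confirmation-bias rule", {
  expect_equal(classify_feedback(0.9, 0.5, chosen = TRUE), "confirmatory")
  expect_equal(classify_feedback(0.2, 0.5, chosen = FALSE), "confirmatory")
  expect_equal(classify_feedback(0.7, 0.5, chosen = FALSE), "disconfirmatory")
  expect_equal(classify_feedback(0.2, 0.5, chosen = TRUE), "disconfirmatory")
  expect_true(is.na(classify_feedback(0.5, 0.5, chosen = TRUE)))
})

test_that("expectancy updates use the rate selected by the classification", {
  q <- update_expectancies(c(A = 0.5, B = 0.5), c(A = 0.9, B = 0.2), "A",
                           alpha_con = 0.5, alpha_dis = 0.1)
  expect_equal(q[["A"]], 0.7)  # chosen, better than expected: confirmatory
  expect_equal(q[["B"]], 0.35) # unchosen, worse than expected: confirmatory
  # alpha = 1 copies v; alpha = 0 leaves q
  expect_equal(update_expectancies(c(A = 0.5, B = 0.4), c(A = 0.9, B = 0.1), "A", 1)[["A"]], 0.9)
  expect_equal(update_expectancies(c(A = 0.5, B = 0.4), c(A = 0.9, B = 0.1), "A", 0),
               c(A = 0.5, B = 0.4))
  # unpresented options untouched
  q <- update_expectancies(c(A = 0.5, B = 0.4, C = 0.3), c(A = 0.9, B = 0.1), "A", 0.5)
  expect_equal(q[["C"]], 0.3)
})

test_that("choice probabilities are softmax with first-position bias, overflow-safe", {
  expect_equal(unname(choice_probabilities(c(0.5, 0.5), beta = 3, bias = 0)), c(0.5, 0.5))
  expect_equal(unname(choice_probabilities(c(0.5, 0.5), beta = 3, bias = log(3))[1]), 0.75)
  expect_equal(unname(choice_probabilities(c(0.1, 0.9, 0.4), beta = 0, bias = 0)),
               rep(1 / 3, 3))
  # overflow-safe for utilities up to +-700
  p <- choice_probabilities(c(7, 0), beta = 100, bias = 0)
  expect_equal(unname(p[1]), 1 / (1 + exp(-700)), tolerance = 1e-12)
  expect_equal(sum(p), 1)
  expect_error(choice_probabilities(c(0.5, 0.5), beta = -1), "beta")
})

test_that("session likelihood equals an independent straight-line trace", {
  task <- load_task_spec("HW2023a")
  set.seed(7)
  for (rep in 1:20) {
    p <- agent_params(omega = runif(1), alpha_con = runif(1), alpha_dis = runif(1),
                      beta_learn = runif(1, 0, 15), beta_transfer = runif(1, 0, 15),
                      bias = runif(1, -2, 2))
    s <- simulate_session(task, p, seed = 5000 + rep)
    s <- s[sample(nrow(s), 10), ] |> dplyr::arrange(trial) # random 10-trial subsession
    expect_equal(session_loglik(s, task, p), oracle_loglik(s, task, p),
                 tolerance = 1e-10)
  }
})

test_that("chance parameters give the closed-form likelihood", {
  s <- simulate_session("V2023", agent_params(beta = 0, bias = 0), seed = 2)
  expect_equal(session_loglik(s, "V2023", agent_params(beta = 0, bias = 0)),
               nrow(s) * log(0.5), tolerance = 1e-12)
})

test_that("the relative model nests the absolute model exactly at omega = 0", {
  task <- load_task_spec("B2018")
  s <- simulate_session(task, default_agents()$rel_confirm, seed = 31)
  abs_m <- model_spec("absolute", 2, 2)
  rel_m <- model_spec("relative", 2, 2)
  theta_abs <- c(0.45, 0.12, 9, 6, 0.8)
  p_abs <- relbandit:::expand_theta(abs_m, theta_abs)
  p_rel <- relbandit:::expand_theta(rel_m, c(0, theta_abs))
  expect_identical(session_loglik(s, task, p_rel), session_loglik(s, task, p_abs))
})

test_that("likelihood is invariant to consistent option renaming", {
  cfg <- yaml::read_yaml(system.file("extdata", "tasks", "V2023.yaml",
                                     package = "relbandit"))
  task <- load_task_spec(cfg)
  p <- default_agents()$abs_confirm
  s <- simulate_session(task, p, seed = 17)
  for (i in seq_along(cfg$contexts))
    for (j in seq_along(cfg$contexts[[i]]$options))
      cfg$contexts[[i]]$options[[j]]$option_id <-
        paste0("Z", cfg$contexts[[i]]$options[[j]]$option_id)
  task2 <- load_task_spec(cfg)
  s2 <- s
  for (col in c("option_1", "option_2", "option_3", "choice"))
    s2[[col]] <- ifelse(is.na(s[[col]]), NA, paste0("Z", s[[col]]))
  expect_equal(session_loglik(s2, task2, p), session_loglik(s, task, p))
})

test_that("invalid learning trials contribute neither likelihood nor updates", {
  task <- toy_task(p1 = 0.25, p2 = 0.75, n_learn = 4)
  s <- simulate_session(task, agent_params(alpha = 0.6, beta = 4), seed = 9)
  s$valid[2] <- FALSE
  p <- agent_params(omega = 0.4, alpha_con = 0.5, alpha_dis = 0.2, beta = 5, bias = 0.3)
  # the oracle skips invalid trials entirely (no likelihood, no update)
  expect_equal(session_loglik(s, task, p), oracle_loglik(s, task, p),
               tolerance = 1e-12)
  # dropping the row gives the same answer: its outcomes never enter Q
  dropped <- s[-2, ]
  expect_equal(session_loglik(dropped, task, p), session_loglik(s, task, p))
})
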