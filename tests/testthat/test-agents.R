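test_that("extreme position bias saturates choice toward the first-listed option", {
  s <- simulate_session("V2023", agent_params(beta = 0, bias = 50), seed = 4)
  expect_true(all(s$choice == s$option_1))
})

test_that("a zero-temperature, zero-bias agent chooses uniformly", {
  t <- toy_task(n_learn = 500)
  s <- simulate_session(t, agent_params(beta = 0, bias = 0), seed = 8)
  rate_a <- mean(s$choice == "A")
  expect_lt(abs(rate_a - 0.5), 3 * sqrt(0.25 / nrow(s)))
})

test_that("position bias monotonically increases the first-listed choice rate", {
  rates <- vapply(c(0, 1, 2), function(b) {
    s <- simulate_session("HW2023a", agent_params(beta = 0, bias = b), seed = 21)
    mean(s$choice == s$option_1)
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("a pure-relative high-temperature learner prefers frequent winners on incongruent pairs", {
  agent <- agent_params(omega = 1, alpha = 0.5, beta = 12, bias = 0)
  sessions <- purrr::map(1:200, function(i)
    simulate_session("HW2023a", agent, seed = 3000 + i,
                     session_id = paste0("r", i))) |> dplyr::bind_rows()
  cb <- congruency_breakdown(sessions, "HW2023a")
  inc <- cb[cb$label == "incongruent", ]
  # higher-relative-value choice rate on incongruent trials = 1 - accuracy
  rate <- 1 - inc$accuracy
  expect_gt(rate, 0.5)
  expect_lt(stats::binom.test(round(rate * inc$n_trials), inc$n_trials,
                              p = 0.5, alternative = "greater")$p.value, 0.05)
})

test_that("the ideal agent maximizes always and matches the ideal choice rate", {
  s <- simulate_ideal("HW2023a", seed = 12)
  acc <- choice_accuracy(s, "HW2023a")
  expect_equal(acc$accuracy[acc$phase == "learning"], 1.0)
  expect_equal(acc$accuracy[acc$phase == "transfer"], 1.0)
  rel <- rel_value_choice_rate(s, "HW2023a")
  expect_equal(rel$rel_rate, ideal_choice_rate("HW2023a"))
})

test_that("the ideal agent flips a fair coin on equal-EV pairs", {
  cfg <- list(name = "tie", currency = "points", transfer_reps = 200,
              contexts = list(
                list(context_id = "c1", n_learning_trials = 10,
                     options = list(
                       list(option_id = "A", kind = "bernoulli", win_prob = 0.5,
                            hi_value = 1, lo_value = 0),
                       list(option_id = "B", kind = "bernoulli", win_prob = 0.2,
                            hi_value = 1, lo_value = 0))),
                list(context_id = "c2", n_learning_trials = 10,
                     options = list(
                       list(option_id = "C", kind = "bernoulli", win_prob = 0.5,
                            hi_value = 1, lo_value = 0),
                       list(option_id = "D", kind = "bernoulli", win_prob = 0.8,
                            hi_value = 1, lo_value = 0)))))
  task <- load_task_spec(cfg)
  s <- simulate_ideal(task, seed = 77)
  ac <- s[s$phase == "transfer" &
            (s$option_1 %in% c("A", "C") & s$option_2 %in% c("A", "C")), ]
  expect_equal(nrow(ac), 200)
  n_a <- sum(ac$choice == "A")
  expect_gt(stats::binom.test(n_a, 200, 0.5)$p.value, 0.001)
})

test_that("grid orchestration is exhaustive, reproducible, and boosts omega in comparison cells", {
  g1 <- simulate_grid("V2023", default_agents()["rel_basic"],
                      c("standard", "comparison"), n_reps = 2, base_seed = 42)
  g2 <- simulate_grid("V2023", default_agents()["rel_basic"],
                      c("standard", "comparison"), n_reps = 2, base_seed = 42)
  expect_identical(g1$manifest, g2$manifest)
  expect_identical(g1$sessions, g2$sessions)
  expect_equal(nrow(g1$manifest), 4)
  expect_equal(length(unique(g1$sessions$session_id)), 4)
  # single-cell grid
  g3 <- simulate_grid("V2023", default_agents()["abs_basic"], "standard",
                      n_reps = 1, base_seed = 1)
  expect_equal(nrow(g3$manifest), 1)
})

test_that("with omega = 0 transfer behavior is invariant to context relabeling that preserves marginals", {
  # reversing the context order in the config changes context labels but not
  # any option's outcome distribution; an absolute encoder's transfer
  # accuracy distribution must be unchanged
  agent <- agent_params(omega = 0, alpha = 0.4, beta = 8)
  cfg <- yaml::read_yaml(system.file("extdata", "tasks", "V2023.yaml",
                                     package = "relbandit"))
  swapped <- cfg
  swapped$contexts <- rev(cfg$contexts)
  rate_for <- function(task) {
    s <- purrr::map(1:40, function(i)
      simulate_session(load_task_spec(task), agent, seed = 100 + i,
                       session_id = paste0("r", i))) |> dplyr::bind_rows()
    acc <- choice_accuracy(s, load_task_spec(task))
    mean(acc$accuracy[acc$phase == "transfer"])
  }
  expect_lt(abs(rate_for(cfg) - rate_for(swapped)), 0.05)
})
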