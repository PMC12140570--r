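test_that("accuracy of the ideal agent is 1 and of a uniform agent about one half", {
  ideal <- simulate_ideal("HW2023a", seed = 2)
  acc <- choice_accuracy(ideal, "HW2023a")
  expect_equal(acc$accuracy, c(1, 1))
  t <- toy_task(n_learn = 500)
  unif <- simulate_session(t, agent_params(beta = 0, bias = 0), seed = 3)
  a <- choice_accuracy(unif, t)
  a_learn <- a$accuracy[a$phase == "learning"]
  expect_lt(abs(a_learn - 0.5), 3 * sqrt(0.25 / 500))
})

test_that("sessions with only equal-EV trials have undefined accuracy", {
  s <- tibble::tibble(
    session_id = "s1", task = "tie", agent = "x", prompt_condition = "standard",
    seed = 1L, trial = 1:2, phase = "transfer", context_id = NA_character_,
    option_1 = c("A", "B"), option_2 = c("B", "A"), option_3 = NA_character_,
    outcome_1 = NA_real_, outcome_2 = NA_real_, outcome_3 = NA_real_,
    choice = c("A", "A"), valid = TRUE)
  tie_task <- load_task_spec(list(
    name = "tie", contexts = list(list(
      context_id = "c1", n_learning_trials = 5,
      options = list(list(option_id = "A", kind = "bernoulli", win_prob = 0.5,
                          hi_value = 1, lo_value = 0),
                     list(option_id = "B", kind = "bernoulli", win_prob = 0.5,
                          hi_value = 1, lo_value = 0))))))
  acc <- choice_accuracy(s, tie_task)
  expect_equal(acc$n_trials, 0)
  expect_true(is.na(acc$accuracy))
})

test_that("ideal sessions hit the ideal rate and a hard-coded rel-chooser hits 1", {
  sessions <- purrr::map(1:5, function(i)
    simulate_ideal("V2023", seed = 40 + i, session_id = paste0("r", i))) |>
    dplyr::bind_rows()
  rel <- rel_value_choice_rate(sessions, "V2023")
  expect_equal(rel$rel_rate, rep(ideal_choice_rate("V2023"), 5))
  # force every transfer choice to the frequent winner
  cls <- classify_transfer_pairs("V2023")
  key <- paste(pmin(cls$option_i, cls$option_j), pmax(cls$option_i, cls$option_j))
  winner <- setNames(cls$rel_winner, key)
  forced <- sessions[sessions$session_id == "r1", ]
  tr <- forced$phase == "transfer"
  k <- paste(pmin(forced$option_1[tr], forced$option_2[tr]),
             pmax(forced$option_1[tr], forced$option_2[tr]))
  forced$choice[tr] <- ifelse(is.na(winner[k]), forced$choice[tr], winner[k])
  expect_equal(rel_value_choice_rate(forced, "V2023")$rel_rate, 1)
})

test_that("congruency identities hold exactly", {
  agent <- agent_params(omega = 0.6, alpha_con = 0.5, alpha_dis = 0.1,
                        beta_learn = 12, beta_transfer = 9, bias = 0.8)
  sessions <- purrr::map(1:10, function(i)
    simulate_session("HW2023a", agent, seed = 60 + i,
                     session_id = paste0("r", i))) |> dplyr::bind_rows()
  cb <- congruency_breakdown(sessions, "HW2023a")
  ann <- sessions[sessions$phase == "transfer", ]
  cls <- classify_transfer_pairs("HW2023a")
  key <- paste(pmin(cls$option_i, cls$option_j), pmax(cls$option_i, cls$option_j))
  lab <- setNames(cls$label, key)
  win <- setNames(cls$rel_winner, key)
  k <- paste(pmin(ann$option_1, ann$option_2), pmax(ann$option_1, ann$option_2))
  # congruent accuracy = higher-rel choice rate on congruent trials
  cong <- k %in% names(lab)[lab == "congruent"]
  expect_equal(cb$accuracy[cb$label == "congruent"],
               mean(ann$choice[cong] == win[k[cong]]))
  # incongruent accuracy = 1 - higher-rel rate on incongruent trials
  inc <- k %in% names(lab)[lab == "incongruent"]
  expect_equal(cb$accuracy[cb$label == "incongruent"],
               1 - mean(ann$choice[inc] == win[k[inc]]))
})

test_that("congruency breakdown is explicit about tasks without incongruent pairs", {
  s <- simulate_ideal("BP2023", seed = 9)
  cb <- congruency_breakdown(s, "BP2023")
  expect_equal(cb$n_trials[cb$label == "incongruent"], 1) # single incongruent pair
  ideal_cb <- congruency_breakdown(simulate_ideal("HW2023a", seed = 10), "HW2023a")
  expect_equal(ideal_cb$accuracy, c(1, 1))
  # a task genuinely without incongruent pairs yields an empty cell
  t <- toy_task()
  cb0 <- congruency_breakdown(simulate_ideal(t, seed = 2), t)
  expect_equal(cb0$n_trials[cb0$label == "incongruent"], 0)
  expect_true(is.na(cb0$accuracy[cb0$label == "incongruent"]))
})

test_that("bias_test applies the t-based decision rule", {
  expect_false(bias_test(rep(0.625, 10), 0.625)$bias)
  b <- bias_test(rep(0.825, 30) + rnorm(30, 0, 1e-4), 0.625)
  expect_true(b$bias)
  # n = 2 uses the t(1) critical value 12.7062
  r <- c(0.6, 0.8)
  b2 <- bias_test(r, 0.5)
  half <- 12.706204736 * sd(r) / sqrt(2)
  expect_equal(b2$ci_lo, mean(r) - half, tolerance = 1e-6)
  expect_equal(b2$ci_hi, mean(r) + half, tolerance = 1e-6)
  # zero spread degenerates to a point interval with strict comparison
  b3 <- bias_test(rep(0.7, 5), 0.625)
  expect_equal(b3$ci_lo, 0.7)
  expect_true(b3$bias)
  expect_error(bias_test(0.5, 0.4), "at least 2")
})

test_that("statistics are invariant to presentation order", {
  s <- simulate_session("V2023", default_agents()$rel_confirm, seed = 33)
  flipped <- s
  flipped$option_1 <- s$option_2
  flipped$option_2 <- s$option_1
  flipped$outcome_1 <- s$outcome_2
  flipped$outcome_2 <- s$outcome_1
  expect_equal(choice_accuracy(flipped, "V2023"), choice_accuracy(s, "V2023"))
  expect_equal(rel_value_choice_rate(flipped, "V2023"),
               rel_value_choice_rate(s, "V2023"))
})

test_that("cell summaries carry the Table-2 decision rule", {
  g <- simulate_grid("V2023", list(rel = default_agents()$rel_confirm,
                                   ideal = "ideal"),
                     "standard", n_reps = 5, base_seed = 8)
  sm <- summarize_bias(g)
  expect_s3_class(sm, "rvb_summary")
  expect_equal(nrow(sm), 2)
  expect_equal(unique(sm$ideal), 0.75)
  ideal_row <- sm[sm$agent == "ideal", ]
  expect_equal(ideal_row$rel_rate, 0.75)
  expect_false(ideal_row$bias)
  expect_true(all(sm$rel_lo <= sm$rel_rate & sm$rel_rate <= sm$rel_hi))
})
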