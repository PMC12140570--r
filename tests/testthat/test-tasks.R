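test_that("built-in tasks match the published structural summaries", {
  expected <- tibble::tribble(
    ~name,      ~n_options, ~n_contexts, ~learning, ~transfer,
    "B2018",    8L, 4L, 48L, 28L,
    "V2023",    4L, 2L, 60L, 12L,
    "HW2023a",  8L, 4L, 60L, 28L,
    "BP2023",  10L, 4L, 60L, 45L,
    "HW2023b",  8L, 4L, 60L, 28L)
  for (i in seq_len(nrow(expected))) {
    task <- load_task_spec(expected$name[i])
    expect_equal(nrow(task$options), expected$n_options[i])
    expect_equal(nrow(task$contexts), expected$n_contexts[i])
    expect_equal(sum(task$contexts$n_learning_trials), expected$learning[i])
    expect_equal(nrow(build_transfer_schedule(task)), expected$transfer[i])
    # contexts partition the option set
    expect_setequal(task$options$context_id, task$contexts$context_id)
    expect_false(anyDuplicated(task$options$option_id) > 0)
  }
  expect_true(all(load_task_spec("BP2023")$contexts$n_members == c(2, 2, 3, 3)))
})

test_that("V2023 uses the published win probabilities and HW2023a the published EVs", {
  v <- load_task_spec("V2023")
  expect_equal(sort(v$options$win_prob), c(0.1, 0.4, 0.6, 0.9))
  hw <- load_task_spec("HW2023a")
  ev <- setNames(expected_value(hw$options), hw$options$option_id)
  expect_equal(ev[["1H"]], 18)
  expect_equal(ev[["2L"]], 21)
  expect_equal(ev[["4L"]], 33)
  expect_true(all(hw$options$sd == 1))
})

test_that("expected_value has the Bernoulli closed form", {
  t <- toy_task(p1 = 0.4, p2 = 0.7)
  expect_equal(expected_value(t$options), c(0.4, 0.7))
  expect_equal(expected_value(load_task_spec("B2018")$options[1, ]),
               0.16666666666666666 * 0 + (1 - 0.16666666666666666) * -1)
})

test_that("invalid configs fail validation naming the violated rule", {
  four <- list(name = "bad", contexts = list(list(
    context_id = "c1", n_learning_trials = 10,
    options = lapply(1:4, function(i)
      list(option_id = paste0("o", i), kind = "bernoulli", win_prob = 0.5,
           hi_value = 1, lo_value = 0)))))
  expect_error(load_task_spec(four), "context_size", class = "relbandit_invalid_task")
  badp <- list(name = "bad2", contexts = list(list(
    context_id = "c1", n_learning_trials = 5,
    options = list(list(option_id = "A", kind = "bernoulli", win_prob = 1.5,
                        hi_value = 1, lo_value = 0),
                   list(option_id = "B", kind = "bernoulli", win_prob = 0.5,
                        hi_value = 1, lo_value = 0)))))
  expect_error(load_task_spec(badp), "win_prob", class = "relbandit_invalid_task")
  expect_error(load_task_spec("NoSuchTask"), "unknown task",
               class = "relbandit_unknown_task")
})

test_that("win_probability matches closed forms, symmetry, and a Monte-Carlo oracle", {
  t <- toy_task(p1 = 0.4, p2 = 0.1)
  expect_equal(win_probability(t$options[1, ], t$options[2, ]), 0.4 * 0.9)
  # identical distributions are exchangeable
  expect_equal(win_probability(t$options[1, ], t$options[1, ]),
               win_probability(t$options[1, ], t$options[1, ]))
  hw <- load_task_spec("HW2023a")
  o18 <- hw$options[hw$options$option_id == "1H", ]
  o15 <- hw$options[hw$options$option_id == "1L", ]
  p_closed <- win_probability(o18, o15)
  set.seed(99)
  n_mc <- 1e6
  p_mc <- mean(rnorm(n_mc, 18, 1) > rnorm(n_mc, 15, 1))
  se <- sqrt(p_mc * (1 - p_mc) / n_mc)
  expect_lt(abs(p_closed - p_mc), 3 * se)
})

test_that("relative_order identifies frequent winners and ties", {
  v <- relative_order(load_task_spec("V2023"), "c1")
  expect_equal(v$relative_rank[v$option_id == "1H"], "higher")
  expect_equal(v$relative_rank[v$option_id == "1L"], "lower")
  # two identical options are tied
  same <- load_task_spec(list(
    name = "same", contexts = list(list(
      context_id = "c1", n_learning_trials = 5,
      options = list(list(option_id = "A", kind = "bernoulli", win_prob = 0.5,
                          hi_value = 1, lo_value = 0),
                     list(option_id = "B", kind = "bernoulli", win_prob = 0.5,
                          hi_value = 1, lo_value = 0))))))
  expect_true(all(relative_order(same)$relative_rank == "tied"))
  # Gaussian: the higher-mean option is the frequent winner
  hw <- relative_order(load_task_spec("HW2023a"), "c1")
  expect_equal(hw$rank_value[hw$option_id == "1H"], 1)
})

test_that("HW2023b frequency/EV conflict contexts rank the lower-EV option higher", {
  t <- tidy(load_task_spec("HW2023b"))
  c3 <- t[t$context_id == "c3", ]
  expect_gt(c3$expected_value[c3$option_id == "3H"],
            c3$expected_value[c3$option_id == "3L"])
  expect_gt(c3$rank_value[c3$option_id == "3L"],
            c3$rank_value[c3$option_id == "3H"])
})
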