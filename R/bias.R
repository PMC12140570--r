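ev_lookup <- function(task) {
  setNames(expected_value(task$options), task$options$option_id)
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

# per-trial helper columns shared by the behavioral statistics
annotate_trials <- function(trials, task) {
  task <- load_task_spec(task)
  evs <- ev_lookup(task)
  cls <- classify_transfer_pairs(task) |>
    mutate(key = pair_key(.data$option_i, .data$option_j))
  ev1 <- evs[trials$option_1]; ev2 <- evs[trials$option_2]
  ev3 <- ifelse(is.na(trials$option_3), NA_real_, evs[trials$option_3])
  ev_top <- pmax(ev1, ev2, ev3, na.rm = TRUE)
  # a trial is an equal-EV trial when the two best presented options tie
  n_at_top <- (abs(ev1 - ev_top) < 1e-9) + (abs(ev2 - ev_top) < 1e-9) +
    ifelse(is.na(ev3), 0, abs(ev3 - ev_top) < 1e-9)
  trials |>
    mutate(ev_chosen = evs[.data$choice],
           ev_max = ev_top,
           ev_tied_trial = n_at_top > 1,
           maximizing = abs(.data$ev_chosen - ev_top) < 1e-9,
           key = ifelse(.data$phase == "transfer",
                        pair_key(.data$option_1, .data$option_2), NA)) |>
    left_join(select(cls, "key", "label", "rel_winner", "ev_winner"), by = "key")
}

#' Choice accuracy (proportion of reward-maximizing choices)
#'
#' Accuracy is the proportion of valid trials on which the chosen option had
#' the highest expected value among those presented. Trials whose two best
#' presented options tie exactly on expected value are excluded from both
#' numerator and denominator; if nothing remains the accuracy is undefined
#' (`NA`), not zero.
#'
#' @param trials Trials tibble (any number of sessions).
#' @param task The task the sessions were run on.
#' @param phases Phases to report (default both, separately).
#' @return Tibble with one row per session x phase: `session_id`, `phase`,
#'   `n_trials` (denominator after exclusions), `accuracy`.
#' @export
choice_accuracy <- function(trials, task, phases = c("learning", "transfer")) {
  ann <- annotate_trials(trials, task) |>
    filter(.data$phase %in% phases)
  ann |>
    mutate(use = .data$valid & !.data$ev_tied_trial & !is.na(.data$choice)) |>
    group_by(.data$session_id, .data$phase) |>
    summarise(n_trials = sum(.data$use),
              accuracy = ifelse(sum(.data$use) > 0,
                                mean(.data$maximizing[.data$use]), NA_real_),
              .groups = "drop")
}

#' Transfer-test rate of choosing the higher-relative-value option
#'
#' For each session, the proportion of valid transfer trials on which the
#' chosen option was the frequent winner of its learning context (see
#' [classify_transfer_pairs()]). Trials whose pair is tied on relative value
#' are excluded - there is no higher-relative-value option to choose.
#' Comparing the mean rate across runs to [ideal_choice_rate()] is the
#' relative-value bias test: an unbiased maximizer cannot exceed the ideal
#' rate on average.
#'
#' @inheritParams choice_accuracy
#' @return Tibble: `session_id`, `n_trials`, `rel_rate`.
#' @export
rel_value_choice_rate <- function(trials, task) {
  ann <- annotate_trials(trials, task) |>
    filter(.data$phase == "transfer", .data$valid, !is.na(.data$choice),
           !is.na(.data$rel_winner))
  ann |>
    group_by(.data$session_id) |>
    summarise(n_trials = n(),
              rel_rate = mean(.data$choice == .data$rel_winner),
              .groups = "drop")
}

#' Test for relative value bias against the ideal agent
#'
#' Computes the mean of run-level choice rates with a t-based confidence
#' interval and flags bias when the interval's lower bound exceeds the
#' ideal agent's rate. With zero variance across runs the interval
#' degenerates to a point and the flag falls back to a strict inequality.
#'
#' @param rates Numeric vector of per-run rates (>= 2 runs).
#' @param ideal_rate The ideal-agent reference ([ideal_choice_rate()]).
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `n_runs`, `mean`, `ci_lo`, `ci_hi`, `ideal`,
#'   `bias`.
#' @export
bias_test <- function(rates, ideal_rate, conf_level = 0.95) {
  rates <- rates[!is.na(rates)]
  n <- length(rates)
  if (n < 2) abort("bias_test requires at least 2 runs")
  m <- mean(rates)
  s <- sd(rates)
  if (s == 0) {
    lo <- hi <- m
  } else {
    half <- qt(1 - (1 - conf_level) / 2, df = n - 1) * s / sqrt(n)
    lo <- m - half; hi <- m + half
  }
  tibble(n_runs = n, mean = m, ci_lo = lo, ci_hi = hi,
         ideal = ideal_rate, bias = lo > ideal_rate)
}

#' Accuracy broken down by transfer-pair congruency
#'
#' Splits transfer accuracy into congruent trials (higher relative value =
#' maximizing choice) and incongruent trials (higher relative value =
#' non-maximizing choice). On incongruent trials accuracy is one minus the
#' higher-relative-value choice rate, so relative value bias appears as
#' selectively poor incongruent accuracy. Tasks without incongruent pairs
#' yield an explicit empty row (`n_trials = 0`, accuracy `NA`).
#'
#' @inheritParams choice_accuracy
#' @return Tibble: `label`, `n_trials`, `n_sessions`, `accuracy`.
#' @export
congruency_breakdown <- function(trials, task) {
  ann <- annotate_trials(trials, task) |>
    filter(.data$phase == "transfer", .data$valid, !is.na(.data$choice),
           .data$label %in% c("congruent", "incongruent"))
  purrr::map(c("congruent", "incongruent"), function(lab) {
    sub <- ann[ann$label == lab, ]
    tibble(label = lab, n_trials = nrow(sub),
           n_sessions = length(unique(sub$session_id)),
           accuracy = if (nrow(sub) > 0) mean(sub$choice == sub$ev_winner) else NA_real_)
  }) |> bind_rows()
}

#' Cell summaries of accuracy and relative-value bias
#'
#' Aggregates a grid of sessions into one row per task x agent x prompt
#' condition: run-level learning and transfer accuracy, the run-level
#' higher-relative-value choice rate with its t-based confidence interval,
#' the ideal-agent reference, and the bias flag (interval entirely above
#' the ideal). Runs are weighted equally (rates are computed per run and
#' then averaged), not by trial counts.
#'
#' @param sessions Trials tibble with `task`, `agent`, `prompt_condition`
#'   columns, or an `rvb_grid` from [simulate_grid()].
#' @param tasks Optional named list of `bandit_task` objects; by default
#'   each task name is loaded with [load_task_spec()].
#' @param conf_level Confidence level for the intervals.
#' @return An `rvb_summary` tibble.
#' @export
summarize_bias <- function(sessions, tasks = NULL, conf_level = 0.95) {
  if (inherits(sessions, "rvb_grid")) sessions <- sessions$sessions
  task_names <- unique(sessions$task)
  tasks <- tasks %||% setNames(purrr::map(task_names, load_task_spec), task_names)
  cells <- distinct(sessions, .data$task, .data$agent, .data$prompt_condition)
  out <- purrr::pmap(cells, function(task, agent, prompt_condition) {
    sub <- sessions[sessions$task == task & sessions$agent == agent &
                    sessions$prompt_condition == prompt_condition, ]
    tk <- tasks[[task]]
    acc <- choice_accuracy(sub, tk)
    rel <- rel_value_choice_rate(sub, tk)
    ideal <- ideal_choice_rate(tk)
    ci <- function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) return(c(mean(v), NA, NA))
      b <- bias_test(v, 0, conf_level)
      c(b$mean, b$ci_lo, b$ci_hi)
    }
    la <- ci(acc$accuracy[acc$phase == "learning"])
    ta <- ci(acc$accuracy[acc$phase == "transfer"])
    rb <- bias_test(rel$rel_rate, ideal, conf_level)
    tibble(task = task, agent = agent, prompt_condition = prompt_condition,
           n_runs = length(unique(sub$session_id)),
           learn_acc = la[1], learn_lo = la[2], learn_hi = la[3],
           transfer_acc = ta[1], transfer_lo = ta[2], transfer_hi = ta[3],
           rel_rate = rb$mean, rel_lo = rb$ci_lo, rel_hi = rb$ci_hi,
           ideal = ideal, bias = rb$bias)
  }) |> bind_rows()
  class(out) <- c("rvb_summary", class(out))
  out
}
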