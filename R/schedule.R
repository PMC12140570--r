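#' Build a learning-phase schedule with exact-frequency outcomes
#'
#' Produces the full learning phase for one run: every context appears
#' exactly `n_learning_trials` times in a seeded random interleaving, every
#' trial carries pre-drawn outcomes for all of its context's members
#' (complete feedback), and the presentation order of the options is
#' re-randomized on every trial (the first-listed option is the one that
#' receives the position bias).
#'
#' For Bernoulli options the outcome sequence is exact-frequency: across the
#' option's learning trials the high outcome occurs exactly
#' `round(win_prob * n)` times (relative frequencies match the underlying
#' probabilities exactly), in seeded random positions. If `win_prob * n` is
#' not an integer it is rounded half-up with a warning; none of the built-in
#' tasks trigger this. Gaussian outcomes are independent seeded draws.
#'
#' @param task A `bandit_task` or anything [load_task_spec()] accepts.
#' @param seed Integer seed; the same seed reproduces the schedule exactly.
#' @return Tibble with one row per learning trial: `trial`, `phase`
#'   (`"learning"`), `context_id`, `option_1..3` (presentation order, `NA`
#'   padding for binary contexts), `outcome_1..3` aligned with the options,
#'   `choice` (`NA`, to be filled by an agent) and `valid`.
#' @examples
#' sched <- build_learning_schedule(load_task_spec("V2023"), seed = 1)
#' table(sched$context_id)
#' @export
build_learning_schedule <- function(task, seed) {
  task <- load_task_spec(task)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  ctx_seq <- sample(rep(task$contexts$context_id, task$contexts$n_learning_trials))
  nt <- length(ctx_seq)

  # pre-draw each option's outcome sequence over its context's trials
  outcome_seq <- purrr::map(seq_len(nrow(task$options)), function(i) {
    o <- task$options[i, ]
    n <- task$contexts$n_learning_trials[task$contexts$context_id == o$context_id]
    if (o$kind == "bernoulli") {
      k_exact <- o$win_prob * n
      k <- round_half_up(k_exact)
      if (abs(k_exact - k) > 1e-9)
        warn(sprintf("win_prob * n = %.6g is not an integer for option '%s'; using %d high outcomes (round half-up)",
                     k_exact, o$option_id, k))
      sample(c(rep(o$hi_value, k), rep(o$lo_value, n - k)))
    } else {
      rnorm(n, o$mean, o$sd)
    }
  }) |> setNames(task$options$option_id)

  members <- split(task$options$option_id, task$options$context_id)
  seen <- setNames(integer(nrow(task$options)), task$options$option_id)
  opt <- matrix(NA_character_, nt, 3)
  out <- matrix(NA_real_, nt, 3)
  for (t in seq_len(nt)) {
    ord <- sample(members[[ctx_seq[t]]])
    for (k in seq_along(ord)) {
      id <- ord[k]
      seen[[id]] <- seen[[id]] + 1L
      opt[t, k] <- id
      out[t, k] <- outcome_seq[[id]][seen[[id]]]
    }
  }
  tibble(trial = seq_len(nt), phase = "learning", context_id = ctx_seq,
         option_1 = opt[, 1], option_2 = opt[, 2], option_3 = opt[, 3],
         outcome_1 = out[, 1], outcome_2 = out[, 2], outcome_3 = out[, 3],
         choice = NA_character_, valid = TRUE)
}

#' Build the transfer-test schedule
#'
#' Enumerates all unordered option pairs, `transfer_reps` times each, in a
#' fixed canonical order (no feedback fields). Session simulators shuffle the
#' trial order and presentation order with their own seed.
#'
#' @inheritParams build_learning_schedule
#' @return Tibble with one row per transfer trial (`phase = "transfer"`,
#'   outcomes `NA`).
#' @examples
#' nrow(build_transfer_schedule("HW2023a")) # choose(8, 2)
#' @export
build_transfer_schedule <- function(task) {
  task <- load_task_spec(task)
  pairs <- utils::combn(task$options$option_id, 2)
  j <- rep(seq_len(ncol(pairs)), each = task$transfer_reps)
  tibble(trial = seq_along(j), phase = "transfer", context_id = NA_character_,
         option_1 = pairs[1, j], option_2 = pairs[2, j], option_3 = NA_character_,
         outcome_1 = NA_real_, outcome_2 = NA_real_, outcome_3 = NA_real_,
         choice = NA_character_, valid = TRUE)
}
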