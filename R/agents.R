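#' Simulate one choice session from a cognitive agent
#'
#' Runs an RL agent generatively through one full session: a seeded
#' learning-phase schedule with exact-frequency complete feedback, followed
#' by the transfer test in seeded random order with per-trial randomized
#' presentation order. Choices are sampled from the softmax probabilities;
#' expectancies start at 0.5, evolve during learning only, and are frozen
#' (with `beta_transfer`) throughout the transfer test.
#'
#' The master `seed` is split into independent sub-seeds for the learning
#' schedule, the transfer ordering and the choice sampling, so any session
#' is reproducible in isolation. Synthetic agents never emit text:
#' `prompt_condition` is carried as metadata only (see [simulate_grid()] for
#' how the comparison-prompt manipulation is emulated).
#'
#' @param task A `bandit_task` or anything [load_task_spec()] accepts.
#' @param agent An [agent_params()] object.
#' @param seed Integer master seed for this session.
#' @param prompt_condition Metadata tag, `"standard"` or `"comparison"`.
#' @param session_id Session identifier; defaults to `"s<seed>"`.
#' @param agent_label Label stored in the `agent` column.
#' @return A trials tibble: one row per trial with session metadata columns
#'   (`session_id`, `task`, `agent`, `prompt_condition`, `seed`) followed by
#'   `trial`, `phase`, `context_id`, `option_1..3` (presentation order; the
#'   first-listed option carries the position bias), `outcome_1..3`,
#'   `choice`, `valid`.
#' @examples
#' s <- simulate_session("V2023", agent_params(alpha = 0.4, beta = 8), seed = 1)
#' dplyr::count(s, phase)
#' @export
simulate_session <- function(task, agent, seed, prompt_condition = "standard",
                             session_id = NULL, agent_label = "model") {
  task <- load_task_spec(task)
  stopifnot(inherits(agent, "agent_params"))
  seeds <- derive_seeds(seed, 3)
  trials <- assemble_schedule(task, seeds[1], seeds[2])
  ed <- engine_data(trials, task)
  pos <- with_session_seed(seeds[3],
    cpp_simulate(as_par_vector(agent), ed$n_options, ed$pres, ed$outc,
                 ed$phase, ed$npres, ed$sess))
  finalize_session(ed$trials, pos + 1L, task, seed, prompt_condition,
                   session_id, agent_label)
}

#' Simulate an ideal reward-maximizing agent
#'
#' The ideal agent always chooses the presented option with the highest
#' expected value (computed from the task's design distributions, not the
#' realized outcomes); exact EV ties are broken by a seeded coin flip. Its
#' transfer-test rate of choosing higher-relative-value options equals
#' [ideal_choice_rate()] by construction, which makes it the reference
#' against which relative value bias is measured.
#'
#' @inheritParams simulate_session
#' @return A trials tibble (see [simulate_session()]).
#' @export
simulate_ideal <- function(task, seed, prompt_condition = "standard",
                           session_id = NULL) {
  task <- load_task_spec(task)
  seeds <- derive_seeds(seed, 3)
  trials <- assemble_schedule(task, seeds[1], seeds[2])
  evs <- setNames(expected_value(task$options), task$options$option_id)
  pos <- with_session_seed(seeds[3], vapply(seq_len(nrow(trials)), function(i) {
    opts <- stats::na.omit(c(trials$option_1[i], trials$option_2[i], trials$option_3[i]))
    ev <- evs[opts]
    best <- which(ev > max(ev) - 1e-12)
    if (length(best) > 1) best <- sample(best, 1)
    as.integer(best[1])
  }, integer(1)))
  finalize_session(trials, pos, task, seed, prompt_condition, session_id, "ideal")
}

assemble_schedule <- function(task, seed_learn, seed_transfer) {
  learning <- build_learning_schedule(task, seed_learn)
  transfer <- build_transfer_schedule(task)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed_transfer)
  transfer <- transfer[sample(nrow(transfer)), ]
  flip <- runif(nrow(transfer)) < 0.5 # per-trial randomized presentation order
  tmp <- transfer$option_1[flip]
  transfer$option_1[flip] <- transfer$option_2[flip]
  transfer$option_2[flip] <- tmp
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  bind_rows(learning, transfer) |> mutate(trial = row_number())
}

with_session_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

finalize_session <- function(trials, choice_pos, task, seed, prompt_condition,
                             session_id, agent_label) {
  opt_mat <- cbind(trials$option_1, trials$option_2, trials$option_3)
  trials$choice <- opt_mat[cbind(seq_len(nrow(trials)), choice_pos)]
  trials$session_id <- session_id %||% paste0("s", seed)
  trials$task <- task$name
  trials$agent <- agent_label
  trials$prompt_condition <- prompt_condition
  trials$seed <- as.integer(seed)
  trials |>
    select("session_id", "task", "agent", "prompt_condition", "seed",
           "trial", "phase", "context_id",
           "option_1", "option_2", "option_3",
           "outcome_1", "outcome_2", "outcome_3", "choice", "valid")
}

#' Default synthetic agent set
#'
#' Four generative agents spanning the factorial of interest: absolute vs.
#' hybrid relative encoding, crossed with a single learning rate vs.
#' confirmation-bias learning rates plus phase-specific temperatures. The
#' confirmation-bias parameterizations sit in the territory of pooled
#' maximum-likelihood estimates reported for instruction-tuned language
#' models on these tasks (`alpha_con ~ 0.5 > alpha_dis ~ 0.15`,
#' `beta_learn ~ 18 > beta_transfer ~ 11`, positive position bias ~ 1.2).
#'
#' @return Named list of four [agent_params()] objects.
#' @export
default_agents <- function() {
  list(
    abs_basic = agent_params(omega = 0, alpha = 0.35, beta = 8, bias = 1),
    abs_confirm = agent_params(omega = 0, alpha_con = 0.5, alpha_dis = 0.15,
                               beta_learn = 18, beta_transfer = 11, bias = 1.2),
    rel_basic = agent_params(omega = 0.3, alpha = 0.35, beta = 8, bias = 1),
    rel_confirm = agent_params(omega = 0.3, alpha_con = 0.5, alpha_dis = 0.15,
                               beta_learn = 18, beta_transfer = 11, bias = 1.2))
}

#' Simulate a full factorial grid of sessions
#'
#' One session per task x agent x prompt-condition x repetition cell, all
#' reproducible from a single base seed (each cell receives its own derived
#' seed). Mirrors the design of running repeated independent experiments
#' with randomly sampled outcome sequences for every combination.
#'
#' Synthetic agents do not read prompts, so the comparison-prompt
#' manipulation - which magnifies relative outcome encoding - is emulated by
#' raising `omega` by `comparison_omega_boost` (capped at 1) for
#' comparison-condition cells of model agents; the `"ideal"` agent is
#' unaffected. Each session draws its own outcome schedule; schedules are
#' not shared across prompt conditions.
#'
#' @param tasks Character vector of task names, or named list of
#'   `bandit_task` objects.
#' @param agents Named list of [agent_params()] objects; the string
#'   `"ideal"` may be used as an element for the ideal agent.
#' @param prompt_conditions Subset of `c("standard", "comparison")`.
#' @param n_reps Sessions per cell.
#' @param base_seed Master seed for the whole grid.
#' @param comparison_omega_boost Added to `omega` in comparison cells.
#' @return An `rvb_grid`: list with `sessions` (all trials, one tibble) and
#'   `manifest` (one row per session: cell factors, derived seed,
#'   session id).
#' @examples
#' g <- simulate_grid("V2023", default_agents()[1], "standard",
#'                    n_reps = 2, base_seed = 1)
#' g$manifest
#' @export
simulate_grid <- function(tasks, agents, prompt_conditions = c("standard", "comparison"),
                          n_reps = 30, base_seed = 1,
                          comparison_omega_boost = 0.15) {
  if (is.character(tasks)) tasks <- setNames(purrr::map(tasks, load_task_spec), tasks)
  if (is.null(names(tasks))) names(tasks) <- purrr::map_chr(tasks, "name")
  if (inherits(agents, "agent_params")) agents <- list(model = agents)
  if (is.null(names(agents)) || any(names(agents) == ""))
    abort("`agents` must be a named list")
  manifest <- tidyr::expand_grid(task = names(tasks), agent = names(agents),
                                 prompt_condition = prompt_conditions,
                                 rep = seq_len(n_reps))
  manifest$seed <- derive_seeds(base_seed, nrow(manifest))
  manifest$session_id <- sprintf("%s.%s.%s.r%02d", manifest$task, manifest$agent,
                                 substr(manifest$prompt_condition, 1, 4), manifest$rep)
  sessions <- purrr::pmap(manifest, function(task, agent, prompt_condition, rep, seed, session_id) {
    a <- agents[[agent]]
    if (identical(a, "ideal"))
      return(simulate_ideal(tasks[[task]], seed, prompt_condition, session_id))
    if (prompt_condition == "comparison")
      a <- agent_params(omega = min(1, a$omega + comparison_omega_boost),
                        alpha_con = a$alpha_con, alpha_dis = a$alpha_dis,
                        beta_learn = a$beta_learn, beta_transfer = a$beta_transfer,
                        bias = a$bias)
    simulate_session(tasks[[task]], a, seed, prompt_condition, session_id,
                     agent_label = agent)
  }) |> bind_rows()
  structure(list(sessions = sessions, manifest = manifest), class = "rvb_grid")
}

#' @export
print.rvb_grid <- function(x, ...) {
  cat(sprintf("<rvb_grid> %d sessions (%d trials) over %d task(s) x %d agent(s) x %d condition(s)\n",
              nrow(x$manifest), nrow(x$sessions),
              length(unique(x$manifest$task)), length(unique(x$manifest$agent)),
              length(unique(x$manifest$prompt_condition))))
  invisible(x)
}
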