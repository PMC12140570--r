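#' Default generating-parameter sampler for recovery simulations
#'
#' Draws one [agent_params()] respecting the model's constraints, from
#' plausible behavioral ranges: `omega ~ U(0.2, 0.8)` for relative models
#' (0 otherwise), a shared learning rate `~ U(0.1, 0.6)` or confirmation-bias
#' rates (`alpha_con ~ U(0.3, 0.7)`, `alpha_dis ~ U(0.02, 0.25)`), inverse
#' temperature(s) `~ U(3, 20)` and position bias `~ U(-2, 2)`.
#'
#' @param model An [model_spec()].
#' @return An [agent_params()] object (uses the current RNG stream).
#' @export
default_param_sampler <- function(model) {
  omega <- if (model$encoding == "relative") runif(1, 0.2, 0.8) else 0
  if (model$n_learning_rates == 2) {
    a_con <- runif(1, 0.3, 0.7); a_dis <- runif(1, 0.02, 0.25)
  } else {
    a_con <- a_dis <- runif(1, 0.1, 0.6)
  }
  b_learn <- runif(1, 3, 20)
  b_transfer <- if (model$n_betas == 2) runif(1, 3, 20) else b_learn
  agent_params(omega = omega, alpha_con = a_con, alpha_dis = a_dis,
               beta_learn = b_learn, beta_transfer = b_transfer,
               bias = runif(1, -2, 2))
}

#' Model-recovery simulation
#'
#' For each generating model: draw parameters, simulate a multi-session
#' dataset, fit all candidate models, and record which one BIC selects.
#' Recovery well above the 1/8 = 12.5% chance level indicates the fitting
#' procedure can tell the family members apart on these tasks; when the
#' wrong model wins it is typically a simpler variant with the same
#' subjective value function.
#'
#' @param tasks Task names or `bandit_task` objects to simulate on.
#' @param sims_per_model Simulated datasets per generating model per task.
#' @param n_sessions Sessions pooled per dataset.
#' @param sampler Function from [model_spec()] to [agent_params()].
#' @param models Candidate set (default all eight; also the generating set).
#' @param n_starts,seed Passed to the fitting stage / master seed.
#' @return An `rvb_recovery`: `matrix` (rows = generating model, columns =
#'   BIC-selected model, entries = counts), `rate` (mean of the diagonal
#'   share), `chance`, and a `details` tibble with one row per dataset.
#' @export
model_recovery <- function(tasks, sims_per_model = 5, n_sessions = 10,
                           sampler = default_param_sampler,
                           models = all_model_specs(),
                           n_starts = 6, seed = 1) {
  if (is.character(tasks)) tasks <- setNames(purrr::map(tasks, load_task_spec), tasks)
  if (is.null(names(tasks))) names(tasks) <- purrr::map_chr(tasks, "name")
  cells <- tidyr::expand_grid(task = names(tasks), generating = names(models),
                              sim = seq_len(sims_per_model))
  cells$seed <- derive_seeds(seed, nrow(cells))
  details <- purrr::pmap(cells, function(task, generating, sim, seed) {
    params <- with_session_seed(seed, sampler(models[[generating]]))
    sess_seeds <- derive_seeds(seed + 1L, n_sessions)
    trials <- purrr::map(seq_len(n_sessions), function(i)
      simulate_session(tasks[[task]], params, sess_seeds[i],
                       session_id = paste0("r", i), agent_label = generating)) |>
      bind_rows()
    cmp <- compare_models(trials, tasks[[task]], models = models,
                          n_starts = n_starts, seed = seed)
    tibble(task = task, generating = generating, sim = sim,
           selected = cmp$best, correct = cmp$best == generating)
  }) |> bind_rows()
  lev <- names(models)
  mat <- table(factor(details$generating, lev), factor(details$selected, lev))
  structure(list(matrix = unclass(mat), rate = mean(details$correct),
                 chance = 1 / length(models), details = details),
            class = "rvb_recovery")
}

#' @export
print.rvb_recovery <- function(x, ...) {
  cat(sprintf("<rvb_recovery> average recovery rate %.1f%% (chance %.1f%%), %d datasets\n",
              100 * x$rate, 100 * x$chance, nrow(x$details)))
  print(x$matrix)
  invisible(x)
}

#' @describeIn model_recovery One row per simulated dataset.
#' @param x An `rvb_recovery`.
#' @param ... Unused.
#' @export
tidy.rvb_recovery <- function(x, ...) x$details

#' Leave-one-run-out cross-validation
#'
#' For each session, fits the model to the pooled data of the remaining
#' sessions and computes the held-out session's log-likelihood. Out-of-
#' sample fit is reported as pseudo-R-squared, `1 - LL_M / LL_0`, where
#' `LL_0` is the log-likelihood of a null model predicting chance
#' probabilities on every trial (1/2 for binary, 1/3 for ternary choices):
#' 0 means chance-level prediction, 1 perfect prediction. Because every run
#' uses an independently drawn outcome sequence, training and test data are
#' independent.
#'
#' @inheritParams fit_model
#' @param params Optional fixed [agent_params()]: evaluate these parameters
#'   out of sample instead of refitting (useful for reference models, e.g.
#'   the chance model `beta = 0, bias = 0` which scores exactly 0).
#' @return An `rvb_cv`: `runs` tibble (`session_id`, `loglik_oos`,
#'   `loglik_chance`, `pseudo_r2`) plus `mean_pseudo_r2`.
#' @export
loo_cv <- function(trials, task, model, n_starts = 10, seed = 1, params = NULL) {
  task <- load_task_spec(task)
  ids <- unique(trials$session_id)
  if (length(ids) < 2 && is.null(params))
    abort("leave-one-run-out needs at least 2 sessions")
  runs <- purrr::map(ids, function(sid) {
    test <- trials[trials$session_id == sid, ]
    p <- params %||%
      fit_model(trials[trials$session_id != sid, ], task, model,
                n_starts = n_starts, seed = seed)$params
    ll <- session_loglik(test, task, p)
    # chance null evaluated through the same accumulator so that the
    # chance model's pseudo-R2 is exactly zero
    ll0 <- session_loglik(test, task, agent_params(beta = 0, bias = 0))
    tibble(session_id = sid, loglik_oos = ll, loglik_chance = ll0,
           pseudo_r2 = 1 - ll / ll0)
  }) |> bind_rows()
  structure(list(runs = runs, mean_pseudo_r2 = mean(runs$pseudo_r2),
                 model = if (is.null(params)) model$name else "fixed"),
            class = "rvb_cv")
}

#' @export
print.rvb_cv <- function(x, ...) {
  cat(sprintf("<rvb_cv> %s: mean out-of-sample pseudo-R2 = %.3f over %d runs\n",
              x$model, x$mean_pseudo_r2, nrow(x$runs)))
  invisible(x)
}

#' @describeIn loo_cv One row per held-out run.
#' @param x An `rvb_cv`.
#' @param ... Unused.
#' @export
tidy.rvb_cv <- function(x, ...) x$runs

#' @describeIn loo_cv One-row summary.
#' @export
glance.rvb_cv <- function(x, ...) {
  tibble(model = x$model, mean_pseudo_r2 = x$mean_pseudo_r2, n_runs = nrow(x$runs))
}
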