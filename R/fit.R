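#' Fit one model to pooled session data by maximum likelihood
#'
#' Estimates a single parameter set for a collection of runs by pooling
#' their log-likelihoods (each session keeps its own expectancy and
#' range-normalization reset). Optimization is bounded multi-start local
#' search: `n_starts` Latin-hypercube start points over the box
#' `omega, alpha in [0, 1]`, `beta in [0, 100]`, `bias in [-10, 10]`,
#' refined with L-BFGS-B; the best converged start wins.
#'
#' @param trials Pooled trials tibble (sessions distinguished by
#'   `session_id`), all from the same task.
#' @param task The task the sessions were run on.
#' @param model An [model_spec()] object.
#' @param n_starts Number of optimization starts.
#' @param seed Seed for the start-point design (with `n_starts = 1` and a
#'   fixed seed the fit is fully deterministic).
#' @return An `rvb_fit`: fitted free parameters (`theta`), the expanded
#'   [agent_params()], `loglik`, `n_obs` (valid choice trials), `k`, `bic`
#'   (`k * log(n_obs) - 2 * loglik`) and per-start diagnostics.
#' @examples
#' \donttest{
#' s <- simulate_grid("V2023", default_agents()["abs_basic"], "standard",
#'                    n_reps = 5, base_seed = 1)
#' fit_model(s$sessions, "V2023", model_spec("absolute"), n_starts = 5, seed = 1)
#' }
#' @export
fit_model <- function(trials, task, model, n_starts = 20, seed = 1) {
  stopifnot(inherits(model, "rl_model_spec"))
  task <- load_task_spec(task)
  ed <- engine_data(trials, task)
  n_obs <- sum(ed$choice >= 0)
  if (n_obs == 0) abort("no valid choice trials to fit")
  bounds <- theta_bounds(model)
  k <- length(bounds$names)
  objective <- function(theta) {
    par <- as_par_vector(expand_theta(model, theta))
    -cpp_loglik(par, ed$n_options, ed$pres, ed$outc, ed$phase, ed$npres,
                ed$sess, ed$choice)
  }
  starts <- with_session_seed(seed, lhs::randomLHS(n_starts, k))
  starts <- sweep(sweep(starts, 2, bounds$upper - bounds$lower, "*"), 2, bounds$lower, "+")
  runs <- purrr::map(seq_len(n_starts), function(i) {
    res <- tryCatch(
      optim(starts[i, ], objective, method = "L-BFGS-B",
            lower = bounds$lower, upper = bounds$upper,
            control = list(maxit = 500, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(res))
      return(tibble(start = i, loglik = NA_real_, convergence = NA_integer_,
                    theta = list(NULL)))
    tibble(start = i, loglik = -res$value, convergence = res$convergence,
           theta = list(res$par))
  }) |> bind_rows()
  ok <- which(is.finite(runs$loglik))
  if (length(ok) == 0)
    abort(paste0("all ", n_starts, " optimization starts failed for model ", model$name),
          class = "relbandit_fit_failed")
  best <- ok[which.max(runs$loglik[ok])]
  theta <- setNames(runs$theta[[best]], bounds$names)
  ll <- runs$loglik[best]
  structure(
    list(model = model, task = task$name,
         theta = theta, params = expand_theta(model, theta),
         loglik = ll, n_obs = n_obs, k = model$k,
         bic = model$k * log(n_obs) - 2 * ll,
         diagnostics = select(runs, -"theta"),
         n_starts = n_starts, seed = seed),
    class = "rvb_fit")
}

#' @export
print.rvb_fit <- function(x, ...) {
  cat(sprintf("<rvb_fit> %s on %s: logLik = %.3f, BIC = %.2f (k = %d, n = %d)\n",
              x$model$name, x$task, x$loglik, x$bic, x$k, x$n_obs))
  print(tidy(x))
  invisible(x)
}

#' @describeIn fit_model One row per fitted free parameter.
#' @param x An `rvb_fit`.
#' @param ... Unused.
#' @export
tidy.rvb_fit <- function(x, ...) {
  tibble(term = names(x$theta), estimate = unname(x$theta))
}

#' @describeIn fit_model One-row model-level summary.
#' @export
glance.rvb_fit <- function(x, ...) {
  tibble(model = x$model$name, logLik = x$loglik, BIC = x$bic, k = x$k,
         n_obs = x$n_obs, n_starts = x$n_starts,
         converged = x$diagnostics$convergence[which.max(x$diagnostics$loglik)] == 0)
}

#' Fit and compare the eight-model family by BIC
#'
#' Fits every candidate model to the same pooled data and ranks them by the
#' Bayesian information criterion (lower is better); exact BIC ties are
#' broken toward the model with fewer parameters.
#'
#' @inheritParams fit_model
#' @param models Named list of [model_spec()] objects (default all eight).
#' @return An `rvb_comparison`: `table` (one row per model, BIC-sorted),
#'   `fits` (named list of `rvb_fit`), `best` (name of the winner).
#' @export
compare_models <- function(trials, task, models = all_model_specs(),
                           n_starts = 20, seed = 1) {
  fits <- purrr::imap(models, function(m, nm)
    fit_model(trials, task, m, n_starts = n_starts, seed = seed))
  table <- purrr::map(fits, glance) |>
    bind_rows() |>
    arrange(.data$BIC, .data$k) |>
    mutate(delta_BIC = .data$BIC - .data$BIC[1])
  structure(list(table = table, fits = fits, best = table$model[1]),
            class = "rvb_comparison")
}

#' @export
print.rvb_comparison <- function(x, ...) {
  cat(sprintf("<rvb_comparison> best by BIC: %s\n", x$best))
  print(x$table)
  invisible(x)
}

#' @describeIn compare_models The BIC table as a tibble.
#' @param x An `rvb_comparison`.
#' @param ... Unused.
#' @export
tidy.rvb_comparison <- function(x, ...) x$table
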