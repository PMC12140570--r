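#' Specify one member of the eight-model RL family
#'
#' The candidate models are the factorial combination of outcome encoding
#' (absolute only, or a free mixture of absolute and relative), one vs. two
#' learning rates (a single rate, or separate confirmatory/disconfirmatory
#' rates), and one vs. two softmax inverse temperatures (shared, or separate
#' learning-phase and transfer-test temperatures). Every model includes the
#' first-listed position bias `b`, so the base parameter count is 3
#' (`alpha`, `beta`, `b`) plus one per enabled factor.
#'
#' @param encoding `"absolute"` (relative weight fixed at 0) or
#'   `"relative"` (mixture weight `omega` estimated freely in `[0, 1]`).
#' @param n_learning_rates 1 (shared) or 2 (`alpha_con`, `alpha_dis`).
#' @param n_betas 1 (shared) or 2 (`beta_learn`, `beta_transfer`).
#' @return An `rl_model_spec` with derived parameter count `k` and a compact
#'   `name` such as `"REL-2a-2b"` (the full relative model).
#' @examples
#' model_spec("relative", 2, 2)
#' @export
model_spec <- function(encoding = c("absolute", "relative"),
                       n_learning_rates = 1, n_betas = 1) {
  encoding <- match.arg(encoding)
  stopifnot(n_learning_rates %in% 1:2, n_betas %in% 1:2)
  rel <- encoding == "relative"
  structure(
    list(encoding = encoding,
         n_learning_rates = as.integer(n_learning_rates),
         n_betas = as.integer(n_betas),
         k = 3L + rel + (n_learning_rates == 2) + (n_betas == 2),
         name = paste0(if (rel) "REL" else "ABS",
                       if (n_learning_rates == 2) "-2a" else "-1a",
                       if (n_betas == 2) "-2b" else "-1b")),
    class = "rl_model_spec")
}

#' @describeIn model_spec All eight candidate models as a named list.
#' @export
all_model_specs <- function() {
  grid <- tidyr::expand_grid(encoding = c("absolute", "relative"),
                             n_learning_rates = 1:2, n_betas = 1:2)
  specs <- purrr::pmap(grid, model_spec)
  setNames(specs, purrr::map_chr(specs, "name"))
}

#' @export
print.rl_model_spec <- function(x, ...) {
  cat(sprintf("<rl_model_spec> %s: %s encoding, %d learning rate(s), %d inverse temperature(s), k = %d\n",
              x$name, x$encoding, x$n_learning_rates, x$n_betas, x$k))
  invisible(x)
}

#' Agent parameters for the RL model family
#'
#' Bundles the full parameter vector of the subjective-value / updating /
#' softmax model: the relative-encoding weight `omega`, confirmatory and
#' disconfirmatory learning rates, learning-phase and transfer-test inverse
#' temperatures, and the first-listed position bias. Constrained variants
#' are expressed by equalities (`alpha_con == alpha_dis`,
#' `beta_learn == beta_transfer`, `omega == 0`).
#'
#' @param omega Relative-encoding weight in `[0, 1]`; 0 is pure absolute
#'   (range-normalized) encoding, 1 pure within-trial relative encoding.
#' @param alpha Shared learning rate in `[0, 1]`; shorthand that sets both
#'   `alpha_con` and `alpha_dis`.
#' @param beta Shared softmax inverse temperature (>= 0); shorthand for both
#'   `beta_learn` and `beta_transfer`.
#' @param bias Additive utility for the first-listed option (any real).
#' @param alpha_con,alpha_dis Learning rates for confirmatory and
#'   disconfirmatory outcomes (see [classify_feedback()]).
#' @param beta_learn,beta_transfer Phase-specific inverse temperatures.
#' @return An `agent_params` object.
#' @examples
#' agent_params(omega = 0.3, alpha_con = 0.5, alpha_dis = 0.15,
#'              beta_learn = 18, beta_transfer = 11, bias = 1.2)
#' @export
agent_params <- function(omega = 0, alpha = 0.3, beta = 5, bias = 0,
                         alpha_con = alpha, alpha_dis = alpha,
                         beta_learn = beta, beta_transfer = beta) {
  p <- list(omega = omega, alpha_con = alpha_con, alpha_dis = alpha_dis,
            beta_learn = beta_learn, beta_transfer = beta_transfer, bias = bias)
  if (!is.finite(p$omega) || p$omega < 0 || p$omega > 1)
    abort("omega must lie in [0, 1]")
  for (a in c("alpha_con", "alpha_dis"))
    if (!is.finite(p[[a]]) || p[[a]] < 0 || p[[a]] > 1)
      abort(paste(a, "must lie in [0, 1]"))
  for (b in c("beta_learn", "beta_transfer"))
    if (!is.finite(p[[b]]) || p[[b]] < 0)
      abort(paste(b, "must be >= 0"))
  if (!is.finite(p$bias)) abort("bias must be finite")
  structure(p, class = "agent_params")
}

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf("<agent_params> omega=%.3g alpha_con=%.3g alpha_dis=%.3g beta_learn=%.3g beta_transfer=%.3g bias=%.3g\n",
              x$omega, x$alpha_con, x$alpha_dis, x$beta_learn, x$beta_transfer, x$bias))
  invisible(x)
}

as_par_vector <- function(params) {
  stopifnot(inherits(params, "agent_params"))
  c(params$omega, params$alpha_con, params$alpha_dis,
    params$beta_learn, params$beta_transfer, params$bias)
}

# free-parameter packing for one model variant ----------------------------

theta_names <- function(model) {
  c(if (model$encoding == "relative") "omega",
    if (model$n_learning_rates == 2) c("alpha_con", "alpha_dis") else "alpha",
    if (model$n_betas == 2) c("beta_learn", "beta_transfer") else "beta",
    "bias")
}

theta_bounds <- function(model) {
  nm <- theta_names(model)
  lower <- c(omega = 0, alpha = 0, alpha_con = 0, alpha_dis = 0,
             beta = 0, beta_learn = 0, beta_transfer = 0, bias = -10)
  upper <- c(omega = 1, alpha = 1, alpha_con = 1, alpha_dis = 1,
             beta = 100, beta_learn = 100, beta_transfer = 100, bias = 10)
  list(lower = unname(lower[nm]), upper = unname(upper[nm]), names = nm)
}

expand_theta <- function(model, theta) {
  nm <- theta_names(model)
  th <- setNames(as.numeric(theta), nm)
  agent_params(
    omega = if (model$encoding == "relative") th[["omega"]] else 0,
    alpha_con = if (model$n_learning_rates == 2) th[["alpha_con"]] else th[["alpha"]],
    alpha_dis = if (model$n_learning_rates == 2) th[["alpha_dis"]] else th[["alpha"]],
    beta_learn = if (model$n_betas == 2) th[["beta_learn"]] else th[["beta"]],
    beta_transfer = if (model$n_betas == 2) th[["beta_transfer"]] else th[["beta"]],
    bias = th[["bias"]])
}
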