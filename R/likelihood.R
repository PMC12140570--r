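#' Encode a trial's outcomes as subjective values
#'
#' Implements the weighted outcome-encoding stage. Each outcome is mapped to
#' `v = (1 - omega) * x_abs + omega * x_rel`, where `x_abs` range-normalizes
#' the outcome by the running minimum/maximum of all rewards experienced so
#' far in the run (the running range absorbs the current trial's outcomes
#' first, so the first trial's extremes map to 0 and 1), and `x_rel`
#' range-normalizes by the outcomes of the current trial only. When a
#' normalizing range is degenerate (max equals min) the normalized value is
#' defined as 0.5. Since `v` is a convex combination of two quantities in
#' `[0, 1]`, it always lies in `[0, 1]`.
#'
#' @param outcomes Named numeric vector of the current trial's outcomes, one
#'   per presented option (complete feedback: at least 2).
#' @param state Encoding state from a previous call (list with `min`,
#'   `max`), or `NULL` at the start of a run.
#' @param omega Relative-encoding weight in `[0, 1]`.
#' @return List with `values` (subjective values, same names as `outcomes`)
#'   and the updated `state`.
#' @examples
#' encode_outcomes(c(a = 20, b = 10), state = list(min = 0, max = 40), omega = 0)
#' @export
encode_outcomes <- function(outcomes, state = NULL, omega) {
  if (!is.finite(omega) || omega < 0 || omega > 1)
    abort("omega must lie in [0, 1]")
  if (length(outcomes) < 2)
    abort("complete feedback requires at least 2 outcomes per trial")
  tmin <- min(outcomes); tmax <- max(outcomes)
  rmin <- min(state$min %||% Inf, tmin)
  rmax <- max(state$max %||% -Inf, tmax)
  x_abs <- if (rmax > rmin) (outcomes - rmin) / (rmax - rmin) else rep(0.5, length(outcomes))
  x_rel <- if (tmax > tmin) (outcomes - tmin) / (tmax - tmin) else rep(0.5, length(outcomes))
  v <- (1 - omega) * x_abs + omega * x_rel
  list(values = setNames(as.numeric(v), names(outcomes)),
       state = list(min = rmin, max = rmax))
}

#' Classify feedback as confirmatory or disconfirmatory
#'
#' A confirmatory outcome is one that supports the agent's choice: the
#' chosen option's outcome is better than expected (positive prediction
#' error) or an unchosen option's outcome is worse than expected.
#' Disconfirmatory outcomes are the reverse. When the subjective value
#' equals the expectancy the prediction error is zero, the update vanishes
#' and the classification is immaterial (`NA`).
#'
#' @param v Subjective value(s) of the outcome.
#' @param q Current expectanc(y/ies).
#' @param chosen Logical: was this the chosen option?
#' @return Character vector: `"confirmatory"`, `"disconfirmatory"` or `NA`.
#' @export
classify_feedback <- function(v, q, chosen) {
  d <- v - q
  out <- ifelse(d == 0, NA_character_,
                ifelse(xor(d < 0, !chosen), "disconfirmatory", "confirmatory"))
  as.character(out)
}

#' Prediction-error update of expectancies
#'
#' Applies the delta rule `Q <- Q + alpha * (v - Q)` to every presented
#' option, selecting `alpha_con` or `alpha_dis` per option according to
#' [classify_feedback()]. Options absent from `v` (not presented this
#' trial) are untouched.
#'
#' @param q Named numeric vector of expectancies.
#' @param v Named numeric vector of subjective values for the presented
#'   options (a subset of `names(q)`).
#' @param chosen_id Name of the chosen option.
#' @param alpha_con,alpha_dis Learning rates in `[0, 1]`.
#' @return Updated named expectancy vector.
#' @examples
#' update_expectancies(c(A = 0.5, B = 0.5), c(A = 0.9, B = 0.2), "A", 0.5, 0.1)
#' @export
update_expectancies <- function(q, v, chosen_id, alpha_con, alpha_dis = alpha_con) {
  stopifnot(all(names(v) %in% names(q)), chosen_id %in% names(v))
  for (id in names(v)) {
    cls <- classify_feedback(v[[id]], q[[id]], id == chosen_id)
    if (is.na(cls)) next
    a <- if (cls == "confirmatory") alpha_con else alpha_dis
    q[[id]] <- q[[id]] + a * (v[[id]] - q[[id]])
  }
  q
}

#' Softmax choice probabilities with first-position bias
#'
#' `p(a_i) = exp(beta * Q_i + b * d_i) / sum_k exp(beta * Q_k + b * d_k)`,
#' where `d_i` indicates the first-listed option. Evaluated with max
#' subtraction, so it is overflow-safe for utilities up to at least +-700.
#'
#' @param q Expectancies of the presented options (length 2 or 3).
#' @param beta Inverse temperature (>= 0).
#' @param bias Additive preference for the first-listed option.
#' @param first Index of the first-listed option (default 1).
#' @return Probability vector summing to 1.
#' @examples
#' choice_probabilities(c(0.5, 0.5), beta = 2, bias = log(3)) # 0.75, 0.25
#' @export
choice_probabilities <- function(q, beta, bias = 0, first = 1L) {
  stopifnot(length(q) %in% 2:3, first %in% seq_along(q))
  if (!is.finite(beta) || beta < 0) abort("beta must be >= 0")
  u <- beta * q
  u[first] <- u[first] + bias
  e <- exp(u - max(u))
  p <- e / sum(e)
  setNames(as.numeric(p), names(q))
}

# Marshal a trials tibble into the flat layout the compiled engine expects.
# Trials are grouped by session (in trial order within a session); a session
# change resets expectancies (Q = 0.5) and the running outcome range.
engine_data <- function(trials, task) {
  task <- load_task_spec(task)
  if (!"session_id" %in% names(trials)) trials$session_id <- "s1"
  trials <- arrange(trials, match(.data$session_id, unique(trials$session_id)), .data$trial)
  ids <- task$options$option_id
  pres <- cbind(match(trials$option_1, ids), match(trials$option_2, ids),
                match(trials$option_3, ids))
  if (anyNA(pres[, 1]) || anyNA(pres[, 2]))
    abort("trials reference options not in the task")
  npres <- as.integer(rowSums(!is.na(pres)))
  outc <- cbind(trials$outcome_1, trials$outcome_2, trials$outcome_3)
  choice_pos <- integer(nrow(trials))
  for (k in 1:3) {
    optk <- trials[[paste0("option_", k)]]
    hit <- !is.na(trials$choice) & !is.na(optk) & trials$choice == optk
    choice_pos[hit] <- k
  }
  valid <- trials$valid %||% rep(TRUE, nrow(trials))
  choice_pos[is.na(trials$choice) | !valid] <- 0L
  list(n_options = length(ids),
       pres = matrix(as.integer(ifelse(is.na(pres), 0L, pres)) - 1L, ncol = 3),
       outc = outc,
       phase = as.integer(trials$phase == "transfer"),
       npres = npres,
       sess = as.integer(factor(trials$session_id, levels = unique(trials$session_id))),
       choice = choice_pos - 1L,
       trials = trials)
}

#' Log-likelihood of recorded choices under one parameterization
#'
#' Replays one or more sessions through the model and sums the log
#' probabilities of the recorded choices over valid trials. At the start of
#' each session expectancies reset to 0.5 and the running outcome range
#' resets; learning trials use `beta_learn` and update expectancies from the
#' recorded complete feedback, transfer trials use `beta_transfer` and leave
#' them frozen. Invalid trials contribute no likelihood term and no update.
#'
#' @param trials A trials tibble (one or more sessions, distinguished by
#'   `session_id`) as produced by [simulate_session()] or read from logs.
#' @param task The task the sessions were run on.
#' @param params An [agent_params()] object.
#' @return The summed log-likelihood (a non-positive number).
#' @examples
#' s <- simulate_session("V2023", agent_params(beta = 0), seed = 1)
#' session_loglik(s, "V2023", agent_params(beta = 0)) # 72 * log(1/2)
#' @export
session_loglik <- function(trials, task, params) {
  ed <- engine_data(trials, load_task_spec(task))
  cpp_loglik(as_par_vector(params), ed$n_options, ed$pres, ed$outc,
             ed$phase, ed$npres, ed$sess, ed$choice)
}
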