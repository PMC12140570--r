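#' Built-in bandit task names
#'
#' The five benchmark task structures shipped with the package. Each pairs a
#' learning phase, in which options are presented in fixed binary or ternary
#' contexts with complete feedback, with a feedback-free transfer test over
#' all option pairs.
#'
#' @return Character vector of task names accepted by [load_task_spec()].
#' @export
builtin_tasks <- function() c("B2018", "V2023", "HW2023a", "BP2023", "HW2023b")

#' Load a bandit task specification
#'
#' Builds a validated `bandit_task` object from a built-in task name, a
#' YAML/JSON config file, or an already-parsed config list. A task consists
#' of options grouped into learning contexts (each option belongs to exactly
#' one context), a per-context learning trial count, and the number of
#' transfer choices per unordered option pair.
#'
#' Built-in tasks are shipped as editable YAML files under
#' `system.file("extdata", "tasks", package = "relbandit")`. The `B2018`,
#' `BP2023` and `HW2023b` distribution parameters are synthetic
#' reconstructions consistent with the published structural summaries (option
#' counts, context structure, reward ranges, ideal-agent choice rates); the
#' `V2023` and `HW2023a` parameters are as published.
#'
#' @param source A built-in task name (see [builtin_tasks()]), a path to a
#'   YAML or JSON config document, or a list with the same structure.
#' @return A `bandit_task` object: a list with `name`, `currency`,
#'   `transfer_reps`, an `options` tibble (one row per option: `option_id`,
#'   `context_id`, `kind`, `win_prob`, `hi_value`, `lo_value`, `mean`, `sd`)
#'   and a `contexts` tibble (`context_id`, `n_members`,
#'   `n_learning_trials`).
#' @examples
#' task <- load_task_spec("V2023")
#' task$options
#' @export
load_task_spec <- function(source) {
  if (inherits(source, "bandit_task")) return(validate_task(source))
  if (is.character(source) && length(source) == 1) {
    if (source %in% builtin_tasks()) {
      path <- system.file("extdata", "tasks", paste0(source, ".yaml"),
                          package = "relbandit", mustWork = TRUE)
      return(validate_task(task_from_config(yaml::read_yaml(path))))
    }
    if (file.exists(source)) {
      cfg <- if (grepl("\\.json$", source)) jsonlite::read_json(source, simplifyVector = FALSE)
             else yaml::read_yaml(source)
      return(validate_task(task_from_config(cfg)))
    }
    abort(paste0("unknown task '", source, "': not a built-in name (",
                 paste(builtin_tasks(), collapse = ", "), ") or existing file"),
          class = "relbandit_unknown_task")
  }
  if (is.list(source)) return(validate_task(task_from_config(source)))
  abort("`source` must be a task name, config path or config list")
}

task_from_config <- function(cfg) {
  need <- c("name", "contexts")
  if (!all(need %in% names(cfg)))
    abort("task config must have fields 'name' and 'contexts'",
          class = "relbandit_invalid_task")
  opt_rows <- purrr::map(cfg$contexts, function(ctx) {
    purrr::map(ctx$options, function(o) {
      tibble(
        option_id = as.character(o$option_id),
        context_id = as.character(ctx$context_id),
        kind = as.character(o$kind),
        win_prob = as.numeric(o$win_prob %||% NA),
        hi_value = as.numeric(o$hi_value %||% NA),
        lo_value = as.numeric(o$lo_value %||% NA),
        mean = as.numeric(o$mean %||% NA),
        sd = as.numeric(o$sd %||% NA)
      )
    }) |> bind_rows()
  }) |> bind_rows()
  ctx_rows <- purrr::map(cfg$contexts, function(ctx) {
    tibble(context_id = as.character(ctx$context_id),
           n_members = length(ctx$options),
           n_learning_trials = as.integer(ctx$n_learning_trials))
  }) |> bind_rows()
  structure(
    list(name = as.character(cfg$name),
         currency = as.character(cfg$currency %||% "points"),
         transfer_reps = as.integer(cfg$transfer_reps %||% 1L),
         options = opt_rows,
         contexts = ctx_rows),
    class = "bandit_task")
}

validate_task <- function(task) {
  fail <- function(rule, msg) abort(paste0("invalid task (", rule, "): ", msg),
                                    class = "relbandit_invalid_task")
  opts <- task$options
  ctxs <- task$contexts
  if (anyDuplicated(opts$option_id))
    fail("unique_option_ids", "option_id values must be unique within a task")
  if (nrow(opts) > 10)
    fail("option_count", "at most 10 options (display letters A-J)")
  if (!all(ctxs$n_members %in% c(2L, 3L)))
    fail("context_size", "every learning context must have 2 or 3 members")
  if (any(ctxs$n_learning_trials < 1))
    fail("learning_trials", "n_learning_trials must be >= 1")
  if (length(unique(ctxs$n_learning_trials)) != 1)
    fail("even_split", "learning trials must be divided evenly among contexts")
  if (task$transfer_reps < 1)
    fail("transfer_reps", "transfer_reps must be >= 1")
  if (!all(opts$kind %in% c("bernoulli", "gaussian")))
    fail("reward_kind", "reward kind must be 'bernoulli' or 'gaussian'")
  bern <- opts[opts$kind == "bernoulli", ]
  if (nrow(bern) > 0) {
    if (any(is.na(bern$win_prob) | bern$win_prob < 0 | bern$win_prob > 1))
      fail("win_prob", "bernoulli win_prob must lie in [0, 1]")
    if (any(is.na(bern$hi_value) | is.na(bern$lo_value) | bern$hi_value <= bern$lo_value))
      fail("hi_lo", "bernoulli hi_value must exceed lo_value")
  }
  gaus <- opts[opts$kind == "gaussian", ]
  if (nrow(gaus) > 0 && any(is.na(gaus$sd) | gaus$sd <= 0))
    fail("sd", "gaussian sd must be positive")
  task
}

#' @export
print.bandit_task <- function(x, ...) {
  cat(sprintf("<bandit_task> %s: %d options, %d contexts (%s), %d learning + %d transfer trials, %s\n",
              x$name, nrow(x$options), nrow(x$contexts),
              paste(x$contexts$n_members, collapse = "+"),
              sum(x$contexts$n_learning_trials),
              n_transfer_trials(x), x$currency))
  print(tidy(x))
  invisible(x)
}

#' @describeIn load_task_spec One row per option with its reward parameters,
#'   expected value and within-context relative rank.
#' @param x A `bandit_task`.
#' @param ... Unused.
#' @export
tidy.bandit_task <- function(x, ...) {
  x$options |>
    mutate(expected_value = expected_value(x$options)) |>
    left_join(relative_order(x), by = c("option_id", "context_id"))
}

n_transfer_trials <- function(task) {
  n <- nrow(task$options)
  as.integer(choose(n, 2) * task$transfer_reps)
}

task_option <- function(task, id) {
  row <- task$options[task$options$option_id == id, ]
  if (nrow(row) != 1) abort(paste0("unknown option_id '", id, "'"))
  row
}

#' Expected value of bandit options
#'
#' @param option A one-row slice of a task's `options` tibble (or any data
#'   frame with columns `kind`, `win_prob`, `hi_value`, `lo_value`, `mean`).
#'   Vectorized over rows.
#' @return Numeric vector of expected rewards in the task currency:
#'   `p * hi + (1 - p) * lo` for Bernoulli options, the mean for Gaussian.
#' @examples
#' expected_value(load_task_spec("HW2023a")$options)
#' @export
expected_value <- function(option) {
  ifelse(option$kind == "bernoulli",
         option$win_prob * option$hi_value + (1 - option$win_prob) * option$lo_value,
         option$mean)
}

#' Probability that one option out-draws another
#'
#' Probability that a single reward drawn from option `opt_i` strictly
#' exceeds an independent draw from option `opt_j`. With Bernoulli rewards
#' ties have positive probability, so `win_probability(i, j)` and
#' `win_probability(j, i)` need not sum to 1.
#'
#' @param opt_i,opt_j One-row option slices (see [expected_value()]).
#' @return A probability in `[0, 1]`.
#' @examples
#' v <- load_task_spec("V2023")$options
#' win_probability(v[2, ], v[1, ]) # 0.4 * 0.9
#' @export
win_probability <- function(opt_i, opt_j) {
  stopifnot(nrow(opt_i) == 1, nrow(opt_j) == 1)
  if (opt_i$kind == "gaussian" && opt_j$kind == "gaussian")
    return(pnorm((opt_i$mean - opt_j$mean) / sqrt(opt_i$sd^2 + opt_j$sd^2)))
  vals_i <- option_support(opt_i)
  if (opt_j$kind == "gaussian")
    return(sum(vals_i$prob * pnorm((vals_i$value - opt_j$mean) / opt_j$sd)))
  vals_j <- option_support(opt_j)
  if (opt_i$kind == "gaussian")
    return(sum(vals_j$prob * (1 - pnorm((vals_j$value - opt_i$mean) / opt_i$sd))))
  sum(outer(vals_i$value, vals_j$value, ">") * outer(vals_i$prob, vals_j$prob))
}

option_support <- function(opt) {
  tibble(value = c(opt$hi_value, opt$lo_value),
         prob = c(opt$win_prob, 1 - opt$win_prob))
}

#' Within-context relative ranks (frequent-winner ordering)
#'
#' Ranks the members of each learning context by how often their draws beat
#' the other members' draws. Option i ranks above option j when
#' `P(draw_i > draw_j) > P(draw_j > draw_i)`; the two are tied when the
#' probabilities are equal. The option that frequently delivers the better
#' local outcome has higher relative value, independently of its absolute
#' expected value. Rank values are normalized to `{0, 1}` in binary contexts
#' and `{0, 0.5, 1}` in ternary contexts.
#'
#' @param task A `bandit_task`.
#' @param context_id Optional single context to rank; default all.
#' @return Tibble with `option_id`, `context_id`, `rank_value` (0 = frequent
#'   loser, 1 = frequent winner) and `relative_rank`
#'   (`"lower"`/`"middle"`/`"higher"`, or `"tied"`).
#' @examples
#' relative_order(load_task_spec("V2023"))
#' @export
relative_order <- function(task, context_id = NULL) {
  task <- load_task_spec(task)
  ids <- context_id %||% task$contexts$context_id
  purrr::map(ids, function(cid) {
    mem <- task$options[task$options$context_id == cid, ]
    m <- nrow(mem)
    beats <- matrix(0, m, m)
    for (i in seq_len(m)) for (j in seq_len(m)) if (i != j) {
      pij <- win_probability(mem[i, ], mem[j, ])
      pji <- win_probability(mem[j, ], mem[i, ])
      beats[i, j] <- sign(pij - pji)
    }
    wins <- rowSums(beats > 0)
    losses <- colSums(beats > 0)
    if (m == 3) {
      # pairwise-majority order must be transitive (a strict linear order or
      # contain genuine ties); a 3-cycle has every option winning exactly once
      if (all(wins == 1) && all(losses == 1))
        abort(paste0("intransitive relative ranking in context '", cid, "'"),
              class = "relbandit_intransitive")
    }
    score <- wins - losses
    rv <- if (length(unique(score)) == 1) rep(0.5, m)
          else (rank(score) - 1) / (m - 1)
    # exact ties within the context share a rank value
    for (s in unique(score)) rv[score == s] <- mean(rv[score == s])
    lab <- dplyr::case_when(
      duplicated(score) | duplicated(score, fromLast = TRUE) ~ "tied",
      rv == 1 ~ "higher",
      rv == 0 ~ "lower",
      TRUE ~ "middle")
    tibble(option_id = mem$option_id, context_id = cid,
           rank_value = rv, relative_rank = lab)
  }) |> bind_rows()
}
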