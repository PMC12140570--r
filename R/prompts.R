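#' Prompt templates for the natural-language task harness
#'
#' The bandit tasks are administered to language models as text: options are
#' "slot machines" labeled with letters, past rounds' outcomes are listed in
#' the prompt, and the model answers in a fixed sentence format. Two designs
#' are supported: the `standard` prompt lists each round's outcomes
#' neutrally, while the `comparison` prompt appends an explicit more/less
#' comparison clause relating each outcome to the first-listed one. The
#' comparison clause wording is configurable; the shipped default is of the
#' form "..., which is more than the $Y delivered by slot machine Z."
#'
#' @param condition `"standard"` or `"comparison"`.
#' @param instruction,outcome_line,comparison_clause,choice_question,response_format
#'   Template strings overriding the defaults. Placeholders in braces
#'   (`{round}`, `{label}`, `{amount}`, `{other_label}`, `{other_amount}`,
#'   `{relation}`, `{options}`) are substituted at render time.
#' @return A `prompt_template` object.
#' @export
prompt_template <- function(condition = c("standard", "comparison"),
                            instruction = NULL, outcome_line = NULL,
                            comparison_clause = NULL, choice_question = NULL,
                            response_format = NULL) {
  condition <- match.arg(condition)
  structure(list(
    condition = condition,
    instruction = instruction %||%
      "You are going to visit four casinos... You are playing slot machines to maximize your total payoff.",
    outcome_line = outcome_line %||%
      "slot machine {label} delivered {amount}",
    comparison_clause = comparison_clause %||%
      ", which is {relation} the {other_amount} delivered by slot machine {other_label}",
    choice_question = choice_question %||%
      "You now face a choice between {options}. Your goal is to maximize payoffs.",
    response_format = response_format %||%
      "Which slot machine do you choose? Give your answer like this: I would choose slot machine _. Do not explain why."),
    class = "prompt_template")
}

fmt_amount <- function(x, currency) {
  sym <- switch(currency, dollars = "$", euros = "€", "")
  amt <- format(x, trim = TRUE, digits = 7)
  if (sym == "") paste(amt, currency) else paste0(sym, amt)
}

sub_all <- function(template, ...) {
  vals <- list(...)
  for (nm in names(vals))
    template <- gsub(paste0("{", nm, "}"), vals[[nm]], template, fixed = TRUE)
  template
}

#' Render a trial's prompt from the session history
#'
#' Builds the full prompt text for one upcoming trial: the instruction, one
#' outcome block per past learning round (every past round appears exactly
#' once, in round order, with option letters honoring each round's
#' presentation order), and the choice question ending in the fixed
#' response-format sentence. In the comparison condition each non-first
#' outcome in a round is related explicitly to the first-listed one
#' (more / less / the same as).
#'
#' @param history Trials tibble of past rounds, learning trials only (rows
#'   with outcomes). Transfer trials carry no feedback, so a history row
#'   that is a transfer trial with outcomes is an error.
#' @param current One trial row (the upcoming choice).
#' @param template A [prompt_template()].
#' @param labels Named character vector mapping `option_id` to display
#'   letter, e.g. from [assign_labels()].
#' @param currency Currency label used to format amounts.
#' @return A single prompt string.
#' @export
render_prompt <- function(history, current, template = prompt_template(),
                          labels, currency = "dollars") {
  if (nrow(history) > 0 && any(history$phase == "transfer" &
        (!is.na(history$outcome_1) | !is.na(history$outcome_2))))
    abort("history contains transfer trials with outcomes; transfer gives no feedback")
  if (nrow(history) > 0 && any(history$phase == "learning" & is.na(history$outcome_1)))
    abort("history learning trials must carry outcomes")
  blocks <- character(0)
  for (r in seq_len(nrow(history))) {
    row <- history[r, ]
    opts <- stats::na.omit(c(row$option_1, row$option_2, row$option_3))
    outs <- c(row$outcome_1, row$outcome_2, row$outcome_3)[seq_along(opts)]
    parts <- vapply(seq_along(opts), function(k)
      sub_all(template$outcome_line, label = labels[[opts[k]]],
              amount = fmt_amount(outs[k], currency)), "")
    if (template$condition == "comparison" && length(opts) > 1) {
      for (k in seq_along(opts)[-1]) {
        rel <- if (outs[k] > outs[1]) "more than"
               else if (outs[k] < outs[1]) "less than" else "the same as"
        parts[k] <- paste0(parts[k],
                           sub_all(template$comparison_clause, relation = rel,
                                   other_amount = fmt_amount(outs[1], currency),
                                   other_label = labels[[opts[1]]]))
      }
    }
    blocks <- c(blocks, paste0("In round ", r, ", ",
                               paste(parts, collapse = ", and "), "."))
  }
  cur_opts <- stats::na.omit(c(current$option_1, current$option_2, current$option_3))
  opt_text <- paste(paste("slot machine", labels[cur_opts]),
                    collapse = if (length(cur_opts) == 2) " and " else ", ")
  paste(c(template$instruction, blocks,
          sub_all(template$choice_question, options = opt_text),
          template$response_format),
        collapse = "\n")
}

#' Assign display letters to task options
#'
#' Letters A-J are randomly assigned to the options at the beginning of each
#' run.
#'
#' @inheritParams build_learning_schedule
#' @return Named character vector: `option_id` -> letter.
#' @export
assign_labels <- function(task, seed) {
  task <- load_task_spec(task)
  with_session_seed(seed,
    setNames(sample(LETTERS[1:10], nrow(task$options)), task$options$option_id))
}

#' Parse a constrained choice response
#'
#' Extracts the chosen letter from the canonical answer sentence
#' ("I would choose slot machine X"), case-insensitively and tolerating
#' trailing punctuation. Anything else - free-form answers, letters that
#' were not offered - is invalid, which is a value (`NA`), not an error.
#'
#' @param response Response text.
#' @param valid_labels Letters of the currently offered options.
#' @return The chosen label, or `NA_character_` if invalid.
#' @examples
#' parse_choice("I would choose slot machine B.", c("B", "E")) # "B"
#' parse_choice("Machine E looks good", c("B", "E"))           # NA
#' @export
parse_choice <- function(response, valid_labels) {
  stopifnot(length(valid_labels) > 0)
  m <- regmatches(response,
                  regexpr("i\\s+would\\s+choose\\s+slot\\s+machine\\s+([A-Ja-j])\\s*[[:punct:]]*\\s*$",
                          response, ignore.case = TRUE, perl = TRUE))
  if (length(m) == 0 || is.na(response)) return(NA_character_)
  label <- toupper(sub(".*slot\\s+machine\\s+([A-Ja-j]).*", "\\1", m, ignore.case = TRUE))
  if (label %in% toupper(valid_labels)) label else NA_character_
}

#' Drop invalid trials and report removal rates
#'
#' Removes trials flagged invalid (or with a missing choice) so they
#' contribute neither to likelihoods nor to behavioral statistics. A
#' dropped learning trial's outcomes are also excluded from expectancy
#' updates - the record lacks a usable choice, so its feedback cannot be
#' classified as confirmatory or disconfirmatory.
#'
#' @param trials Trials tibble with `valid` flags.
#' @return List with `trials` (invalid rows removed) and `report` (one row
#'   per task x agent x prompt-condition cell: `n_trials`, `n_removed`,
#'   `removal_rate`).
#' @export
filter_invalid <- function(trials) {
  bad <- !trials$valid | is.na(trials$choice)
  grp <- intersect(c("task", "agent", "prompt_condition"), names(trials))
  report <- trials |>
    mutate(bad = bad) |>
    group_by(dplyr::across(dplyr::all_of(grp))) |>
    summarise(n_trials = n(), n_removed = sum(.data$bad),
              removal_rate = mean(.data$bad), .groups = "drop")
  list(trials = trials[!bad, ], report = report)
}
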