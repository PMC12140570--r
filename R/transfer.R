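#' Classify transfer pairs by expected-value / relative-value congruency
#'
#' Labels every unordered pair of task options by whether the expected-value
#' maximizing option coincides with the option of higher relative value
#' (the frequent winner of its learning context, see [relative_order()]):
#'
#' * `congruent` — the higher-relative-value option is also the EV-maximizing
#'   choice; an ideal agent picks the higher-relative-value option.
#' * `incongruent` — the higher-relative-value option is the non-maximizing
#'   choice; an ideal agent avoids it.
#' * `rel_tied` — the two options share the same relative rank value, so a
#'   "higher relative value" choice is undefined.
#' * `ev_tied` — relative ranks differ but expected values tie exactly, so
#'   the maximizing choice is undefined. Flagged via `ev_tied` and excluded
#'   from the ideal choice rate; no built-in task produces one.
#'
#' @inheritParams build_learning_schedule
#' @return Tibble with one row per unordered pair: `option_i`, `option_j`,
#'   `ev_i`, `ev_j`, `ev_winner` (`NA` if tied), `rank_i`, `rank_j`,
#'   `rel_winner` (`NA` if tied), `label`, `ev_tied`.
#' @examples
#' dplyr::count(classify_transfer_pairs("HW2023a"), label)
#' @export
classify_transfer_pairs <- function(task) {
  task <- load_task_spec(task)
  ord <- relative_order(task)
  info <- task$options |>
    mutate(ev = expected_value(task$options)) |>
    left_join(select(ord, "option_id", "rank_value"), by = "option_id")
  pairs <- utils::combn(info$option_id, 2)
  purrr::map(seq_len(ncol(pairs)), function(k) {
    i <- info[info$option_id == pairs[1, k], ]
    j <- info[info$option_id == pairs[2, k], ]
    ev_tie <- isTRUE(all.equal(i$ev, j$ev, tolerance = 1e-12)) || i$ev == j$ev
    rel_tie <- i$rank_value == j$rank_value
    ev_winner <- if (ev_tie) NA_character_ else if (i$ev > j$ev) i$option_id else j$option_id
    rel_winner <- if (rel_tie) NA_character_ else if (i$rank_value > j$rank_value) i$option_id else j$option_id
    label <- if (rel_tie) "rel_tied"
             else if (ev_tie) "ev_tied"
             else if (identical(ev_winner, rel_winner)) "congruent"
             else "incongruent"
    tibble(option_i = i$option_id, option_j = j$option_id,
           ev_i = i$ev, ev_j = j$ev, ev_winner = ev_winner,
           rank_i = i$rank_value, rank_j = j$rank_value, rel_winner = rel_winner,
           label = label, ev_tied = ev_tie)
  }) |> bind_rows()
}

#' Ideal-agent choice rate for higher-relative-value options
#'
#' The rate at which an ideal, reward-maximizing agent (one that always
#' selects the option with the higher expected value) would choose the
#' option with higher relative value in the transfer test. Pairs with tied
#' relative values are excluded (the comparison is undefined), as are pairs
#' with exactly tied expected values. Because every pair appears equally
#' often in the transfer schedule, the rate is the fraction of remaining
#' pairs that are congruent and is invariant to `transfer_reps`.
#'
#' An empirical choice rate above this reference indicates relative value
#' bias: the agent picks frequent winners even when they pay less.
#'
#' @inheritParams build_learning_schedule
#' @return A proportion in `[0, 1]`.
#' @examples
#' ideal_choice_rate("V2023") # 0.750
#' @export
ideal_choice_rate <- function(task) {
  cls <- classify_transfer_pairs(task)
  use <- cls$label %in% c("congruent", "incongruent")
  if (!any(use))
    abort("no transfer pairs with distinct relative and expected values",
          class = "relbandit_no_pairs")
  mean(cls$label[use] == "congruent")
}
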