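#' Read and write session logs
#'
#' Sessions are serialized as JSON Lines: one trial per line with the flat
#' schema of [simulate_session()] (`session_id`, `task`, `agent`,
#' `prompt_condition`, `seed`, `trial`, `phase`, `context_id`,
#' `option_1..3`, `outcome_1..3`, `choice`, `valid`). The reader accepts the
#' same format for externally produced logs (e.g. real language-model runs),
#' filling any missing schema columns with `NA`.
#'
#' @param trials Trials tibble.
#' @param path File path (`.jsonl`).
#' @return `write_sessions()` returns `path` invisibly; `read_sessions()` a
#'   trials tibble.
#' @export
write_sessions <- function(trials, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  jsonlite::stream_out(as.data.frame(trials), con, verbose = FALSE, na = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname write_sessions
#' @export
read_sessions <- function(path) {
  df <- jsonlite::stream_in(file(path), verbose = FALSE)
  schema <- c(session_id = "character", task = "character", agent = "character",
              prompt_condition = "character", seed = "integer",
              trial = "integer", phase = "character", context_id = "character",
              option_1 = "character", option_2 = "character", option_3 = "character",
              outcome_1 = "double", outcome_2 = "double", outcome_3 = "double",
              choice = "character", valid = "logical")
  for (nm in names(schema)) {
    if (!nm %in% names(df)) df[[nm]] <- rep(NA, nrow(df))
    mode_fun <- switch(schema[[nm]], character = as.character, integer = as.integer,
                       double = as.numeric, logical = as.logical)
    df[[nm]] <- mode_fun(df[[nm]])
  }
  as_tibble(df[, names(schema)])
}

#' @rdname write_sessions
#' @param manifest Manifest tibble (one row per session).
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(manifest, path)
  invisible(path)
}

#' @rdname write_sessions
#' @export
read_manifest <- function(path) readr::read_csv(path, show_col_types = FALSE)
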