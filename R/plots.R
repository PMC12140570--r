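#' Plot cell summaries of relative-value bias
#'
#' Run-level mean choice rates for higher-relative-value options with their
#' confidence intervals, against the ideal-agent reference (open
#' diamonds). Cells whose interval sits entirely above the ideal are the
#' biased ones.
#'
#' @param object An `rvb_summary` from [summarize_bias()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rvb_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$task, y = .data$rel_rate,
                                       colour = .data$agent)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$rel_lo, ymax = .data$rel_hi),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$ideal), shape = 5, size = 3,
                        colour = "black") +
    ggplot2::facet_wrap(~prompt_condition) +
    ggplot2::labs(y = "choice rate, higher relative value", x = NULL,
                  title = "Relative value bias vs. ideal agent") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a model-recovery confusion matrix
#'
#' @param object An `rvb_recovery` from [model_recovery()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rvb_recovery <- function(object, ...) {
  df <- as.data.frame.table(object$matrix, responseName = "count")
  names(df)[1:2] <- c("generating", "selected")
  df$prop <- df$count / rowSums(object$matrix)[df$generating]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$selected, y = .data$generating,
                                   fill = .data$prop)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue", limits = c(0, 1)) +
    ggplot2::labs(x = "selected by BIC", y = "generating model", fill = "recovery",
                  title = sprintf("Model recovery (average %.0f%%, chance %.1f%%)",
                                  100 * object$rate, 100 * object$chance)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a BIC model-comparison table
#'
#' @param object An `rvb_comparison` from [compare_models()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rvb_comparison <- function(object, ...) {
  df <- object$table
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$model, .data$delta_BIC),
                                   y = .data$delta_BIC)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(Delta * "BIC from best"),
                  title = paste("Best model:", object$best)) +
    ggplot2::theme_minimal()
}

#' Plot probe significance counts
#'
#' Number of hidden units with significant partial coefficients for the
#' absolute-value difference only, the relative-value difference only, or
#' both, after the applied correction.
#'
#' @param object An `rvb_probe`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rvb_probe <- function(object, ...) {
  df <- tibble(bucket = factor(names(object$counts), names(object$counts)),
               count = as.integer(object$counts))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bucket, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "significant units",
                  title = sprintf("Value coding in hidden units (%s correction)",
                                  object$correction)) +
    ggplot2::theme_minimal()
}
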