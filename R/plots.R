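# ggplot2 views of triage output.

#' Plot flagged-variant counts by mechanism
#'
#' Bar chart of a per-category flag-count table (trio-mode inherited /
#' de novo columns, or a single proband-only column), e.g. from
#' [summarize_flags()] or [reference_flag_counts()].
#'
#' @param counts Count tibble with a `category` column and numeric count
#'   columns.
#' @return A ggplot object.
#' @export
plot_flag_counts <- function(counts) {
  long <- tidyr::pivot_longer(counts,
                              cols = dplyr::where(is.numeric),
                              names_to = "analysis", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$category, y = .data$n,
                                     fill = .data$analysis)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_log10() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "flagged variants (log scale)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Autoplot a cohort summary
#'
#' Per-class predictive value of the flag and diagnostic yield.
#'
#' @param object A `cohort_summary` from [review_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_summary <- function(object, ...) {
  d <- tidy(object)
  d$class <- paste(d$variant_class, d$inheritance_class)
  long <- tidyr::pivot_longer(
    d[, c("class", "predictive_value", "diagnostic_yield")],
    cols = c("predictive_value", "diagnostic_yield"),
    names_to = "measure", values_to = "pct")
  ggplot2::ggplot(long[!is.na(long$pct), ],
                  ggplot2::aes(x = .data$class, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~measure, scales = "free_x") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "percent") +
    ggplot2::theme_minimal()
}
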