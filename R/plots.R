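# ggplot2 visualisations of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Contribution-score bar chart of the top-ranked features
#'
#' @param object A `loc_ranking`.
#' @param top_n Number of leading features to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot loc_ranking
#' @export
autoplot.loc_ranking <- function(object, top_n = 45L, ...) {
  df <- utils::head(tibble::as_tibble(unclass(object)), top_n)
  df$column <- factor(df$column, levels = rev(df$column))
  finite <- df$score[is.finite(df$score)]
  cap <- if (length(finite) > 0) max(finite) * 1.1 else 1
  df$plotted <- pmin(df$score, cap)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$plotted, y = .data$column)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "F-score (contribution score)", y = NULL,
                  title = sprintf("Top %d features", nrow(df))) +
    ggplot2::theme_minimal()
}

#' Per-location accuracy and MCC chart of an evaluation report
#'
#' @param object A `loc_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot loc_report
#' @export
autoplot.loc_report <- function(object, ...) {
  df <- object$per_class |>
    dplyr::filter(!is.na(.data$accuracy)) |>
    dplyr::select("location", "accuracy", "mcc") |>
    tidyr::pivot_longer(c("accuracy", "mcc"), names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$location)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("Jackknife performance (OA %.1f%%, absolute-true %.1f%%)",
                      100 * object$oa, 100 * object$absolute_true)) +
    ggplot2::theme_minimal()
}
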