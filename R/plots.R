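#' @export
autoplot.correlation_curve <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$distance_bp / 1e3, y = .data$r)
  ) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$defined), size = 1) +
    ggplot2::scale_shape_manual(
      values = c(`TRUE` = 16, `FALSE` = 1), guide = "none"
    ) +
    ggplot2::labs(
      x = "Genomic distance (kb)",
      y = "Pearson correlation (true vs predicted)",
      title = "Distance-stratified correlation"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.di_profile <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$start / 1e6, y = .data$di)
  ) +
    ggplot2::geom_col(
      ggplot2::aes(fill = .data$di > 0),
      width = 0.9 * (attr(object, "resolution") %||% 5000) / 1e6
    ) +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "navy"), guide = "none"
    ) +
    ggplot2::labs(
      x = "Position (Mb)", y = "Directionality index",
      title = "Directionality index profile"
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a contact table
#'
#' Upper-triangle sparse counts rendered as a (log-scaled) tile heatmap;
#' handy for eyeballing planted domains and loops in synthetic studies.
#'
#' @param table A [contact_table()].
#' @param max_distance_bins Optional radius restriction for display.
#' @return A ggplot object.
#' @export
plot_contact_matrix <- function(table, max_distance_bins = NULL) {
  res <- contact_resolution(table)
  df <- as_tibble(table) |> filter(.data$measured)
  if (!is.null(max_distance_bins)) {
    df <- df |> filter((.data$start2 - .data$start1) / res <= max_distance_bins)
  }
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$start1 / 1e6, y = .data$start2 / 1e6,
                 fill = log1p(.data$count))
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log1p(count)") +
    ggplot2::labs(x = "Bin 1 (Mb)", y = "Bin 2 (Mb)") +
    ggplot2::theme_minimal()
}

#' Bar chart of feature importances
#'
#' @param importance Tibble with `feature` and a score column (`importance`
#'   or `count`), e.g. from [oob_importance()] or [usage_importance()].
#' @param top_n Number of features shown (default 20).
#' @return A ggplot object.
#' @export
plot_importance <- function(importance, top_n = 20) {
  score_col <- intersect(c("importance", "count"), names(importance))[1L]
  if (is.na(score_col)) {
    stop_arg("`importance` needs an `importance` or `count` column")
  }
  df <- importance |>
    arrange(desc(.data[[score_col]])) |>
    head(top_n)
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data[[score_col]],
      y = stats::reorder(.data$feature, .data[[score_col]])
    )
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = score_col, y = NULL, title = "Feature importance") +
    ggplot2::theme_minimal()
}
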