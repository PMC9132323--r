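# Plotting: four-condition bar charts and learning-dynamics curves.

#' Bar chart of per-condition performance
#'
#' One bar per test condition (Both, Conflict, Shape, Non-shape), with a
#' dashed line at chance and optional 95% confidence error bars when the
#' report contains several learners or seeds.
#'
#' @param report Condition-report tibble with columns `condition` and the
#'   metric column; optionally a `learner` or `seed` column to aggregate
#'   over.
#' @param metric Metric column to plot (default `"accuracy"`).
#' @param chance Chance level (default 0.2).
#' @return A ggplot object.
#' @export
plot_condition_report <- function(report, metric = "accuracy", chance = 0.2) {
  conds <- intersect(TEST_CONDITIONS, unique(report$condition))
  agg <- report |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(mean = mean(.data[[metric]]),
                     ci = ci95(.data[[metric]]), .groups = "drop") |>
    dplyr::mutate(condition = factor(.data$condition, levels = conds))
  p <- ggplot2::ggplot(agg, ggplot2::aes(x = .data$condition, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = chance, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
  if (any(!is.na(agg$ci)))
    p <- p + ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean - .data$ci, ymax = .data$mean + .data$ci), width = 0.2)
  p
}

#' Learning-dynamics curves
#'
#' Per-condition performance against training amount (trials for the ideal
#' observer, epochs for the network).
#'
#' @param curves Tibble with columns `checkpoint`, `condition` and the
#'   metric column (as returned by [learning_curve()]).
#' @param metric Metric column to plot.
#' @param chance Chance level.
#' @return A ggplot object.
#' @export
plot_learning_curve <- function(curves, metric = "mean_posterior", chance = 0.2) {
  ggplot2::ggplot(curves, ggplot2::aes(
    x = .data$checkpoint, y = .data[[metric]], colour = .data$condition)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = chance, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "training trials", y = metric, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Display a rendered stimulus
#'
#' @param img Raster array from [render_stimulus()].
#' @return A ggplot object showing the image.
#' @export
plot_stimulus <- function(img) {
  df <- expand.grid(y = seq_len(dim(img)[1]), x = seq_len(dim(img)[2]))
  df$col <- grDevices::rgb(img[, , 1], img[, , 2], img[, , 3])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = -.data$y, fill = .data$col)) +
    ggplot2::geom_raster() + ggplot2::scale_fill_identity() +
    ggplot2::coord_fixed() + ggplot2::theme_void()
}
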