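#' Plot learning curves
#'
#' Group mean +/- SEM time course of a metric over training days, one line
#' per group.
#'
#' @param summaries Summary table with `day`, the metric column, and a
#'   grouping column.
#' @param metric Column to plot.
#' @param by Grouping column (default `"genotype"`).
#' @return A ggplot object.
#' @export
plot_learning_curves <- function(summaries, metric, by = "genotype") {
  curves <- learning_curves(summaries, metric)
  agg <- dplyr::summarise(
    dplyr::group_by(curves, .data[[by]], .data$day),
    mean = mean(.data$value, na.rm = TRUE),
    sem = sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value))),
    .groups = "drop"
  )
  ggplot2::ggplot(agg, ggplot2::aes(
    x = .data$day, y = .data$mean,
    colour = .data[[by]], group = .data[[by]]
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem, fill = .data[[by]]),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = sort(unique(agg$day))) +
    ggplot2::labs(x = "Training day", y = metric) +
    ggplot2::theme_classic()
}

#' Plot the final-day outcome distribution
#'
#' Stacked distribution of targeted-reach outcomes per group (the bar
#' equivalent of an outcome pie chart).
#'
#' @param dist Output of [outcome_distribution()].
#' @param by Grouping column used when building `dist`.
#' @return A ggplot object.
#' @export
plot_outcome_distribution <- function(dist, by = "genotype") {
  ggplot2::ggplot(dist, ggplot2::aes(
    x = .data[[by]], y = .data$fraction, fill = .data$label
  )) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::scale_fill_manual(values = c(
      success = "#2e8b57", complete_miss = "#c0392b",
      contact_miss = "#e67e22", other = "#85c1e9"
    )) +
    ggplot2::labs(x = NULL, y = "Fraction of targeted reaches") +
    ggplot2::theme_classic()
}

#' Overlay reach trajectories
#'
#' Cumulative overlay of detected reach paths. Analysis always uses the raw
#' coordinates; `spline = TRUE` interpolates each path for display only.
#'
#' @param detections Per-reach table with a `points` list-column (e.g.
#'   `pipeline$detections`).
#' @param pellet Optional (x, y) pellet coordinate drawn as a reference dot.
#' @param spline Spline-interpolate paths for display (default FALSE).
#' @param max_reaches Cap on the number of overlaid reaches.
#' @return A ggplot object.
#' @export
plot_reach_trajectories <- function(detections, pellet = NULL, spline = FALSE,
                                    max_reaches = 200) {
  det <- utils::head(detections, max_reaches)
  paths <- purrr::imap(det$points, function(p, i) {
    if (spline && nrow(p) >= 4) {
      sx <- stats::spline(seq_len(nrow(p)), p$x, n = 10 * nrow(p))
      sy <- stats::spline(seq_len(nrow(p)), p$y, n = 10 * nrow(p))
      tibble::tibble(reach = i, x = sx$y, y = sy$y)
    } else {
      tibble::tibble(reach = i, x = p$x, y = p$y)
    }
  })
  paths <- dplyr::bind_rows(paths)
  pl <- ggplot2::ggplot(paths, ggplot2::aes(
    x = .data$x, y = .data$y, group = .data$reach
  )) +
    ggplot2::geom_path(alpha = 0.25, linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px, image convention)") +
    ggplot2::theme_classic()
  if (!is.null(pellet)) {
    pl <- pl + ggplot2::annotate(
      "point", x = pellet[1], y = pellet[2], colour = "red", size = 2
    )
  }
  pl
}

#' @describeIn plot_learning_curves autoplot method for pipeline results
#'   (success by targeted reach by default).
#' @param object A `reach_pipeline`.
#' @param ... Passed to [plot_learning_curves()].
#' @export
autoplot.reach_pipeline <- function(object, metric = "pct_success_by_reach",
                                    ...) {
  plot_learning_curves(object$summaries, metric, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
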