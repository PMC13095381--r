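#' Total path length of a reach
#'
#' Sum of Euclidean step lengths along the reach's point sequence, in pixels.
#' At least two samples are required.
#'
#' @param reach Data frame with `x` and `y` columns (one reach's points).
#' @return Path length in pixels.
#' @export
reach_path_length <- function(reach) {
  if (nrow(reach) < 2) abort("path length undefined for a reach with < 2 samples")
  sum(sqrt(diff(reach$x)^2 + diff(reach$y)^2))
}

#' Vertical spread of a reach
#'
#' Difference between the maximum and minimum y-coordinate of the reach's
#' samples, in pixels.
#'
#' @inheritParams reach_path_length
#' @return Delta-Y in pixels (>= 0).
#' @export
reach_delta_y <- function(reach) {
  if (nrow(reach) < 1) abort("delta-Y undefined for an empty reach")
  max(reach$y) - min(reach$y)
}

#' Maximal horizontal extension of a reach beyond the slit
#'
#' Maximum over samples of the signed displacement from the slit plane in
#' the reach direction, floored at zero (a paw behind the slit contributes
#' nothing).
#'
#' @inheritParams reach_path_length
#' @param slit_x Pixel x-coordinate of the slit plane.
#' @param toward_sign +1 if the pellet lies at larger x than the slit,
#'   -1 otherwise.
#' @return Delta-X in pixels (>= 0).
#' @export
reach_delta_x <- function(reach, slit_x, toward_sign = 1) {
  if (nrow(reach) < 1) abort("delta-X undefined for an empty reach")
  if (!toward_sign %in% c(-1, 1)) abort("toward_sign must be +1 or -1")
  max(0, max(toward_sign * (reach$x - slit_x)))
}

#' Per-reach kinematics table
#'
#' Computes path length, delta-Y, delta-X and duration for every reach in a
#' detection table, on the reach interval only (outward start to retraction
#' onset).
#'
#' @param reaches Tibble with a `points` list-column of `frame, x, y` tibbles
#'   (as returned by [find_reaches()], possibly carrying `subject`, `day`,
#'   `trial`, `ordinal` columns).
#' @param slit_x Pixel x-coordinate of the slit plane.
#' @param toward_sign Reach direction along x (+1 or -1).
#' @param fps Frames per second, used for durations.
#' @param distance_metric `"path"` (default) sums Euclidean step lengths;
#'   `"chord"` uses the straight-line first-to-last distance instead.
#' @return `reaches` with added columns `path_length_px`, `delta_y_px`,
#'   `delta_x_px`, `duration_s`.
#' @export
reach_kinematics <- function(reaches, slit_x, toward_sign = 1, fps = 240,
                             distance_metric = c("path", "chord")) {
  distance_metric <- match.arg(distance_metric)
  pts <- reaches$points
  dist_fun <- if (distance_metric == "path") {
    reach_path_length
  } else {
    function(r) sqrt((r$x[nrow(r)] - r$x[1])^2 + (r$y[nrow(r)] - r$y[1])^2)
  }
  dplyr::mutate(
    reaches,
    path_length_px = purrr::map_dbl(pts, dist_fun),
    delta_y_px = purrr::map_dbl(pts, reach_delta_y),
    delta_x_px = purrr::map_dbl(pts, reach_delta_x, slit_x = slit_x,
                                toward_sign = toward_sign),
    duration_s = (.data$end_frame - .data$start_frame) / fps
  )
}

#' Aggregate kinematics per subject and day
#'
#' Arithmetic means of the per-reach metrics within each subject-day.
#' Subject-days present in `grid` but with zero reaches yield missing values
#' (not zeros), so they propagate to the statistics stage as missing data.
#'
#' @param kin Per-reach table from [reach_kinematics()] carrying `subject`
#'   and `day` columns.
#' @param grid Optional tibble of `subject`, `day` combinations to complete;
#'   combinations absent from `kin` get `NA` means and `n_reaches = 0`.
#' @return Tibble with one row per subject-day: mean `path_length_px`,
#'   `delta_y_px`, `delta_x_px`, and `n_reaches`.
#' @export
aggregate_kinematics <- function(kin, grid = NULL) {
  agg <- dplyr::summarise(
    dplyr::group_by(kin, .data$subject, .data$day),
    path_length_px = mean(.data$path_length_px),
    delta_y_px = mean(.data$delta_y_px),
    delta_x_px = mean(.data$delta_x_px),
    n_reaches = dplyr::n(),
    .groups = "drop"
  )
  if (!is.null(grid)) {
    agg <- dplyr::left_join(
      dplyr::distinct(tibble::as_tibble(grid), .data$subject, .data$day),
      agg,
      by = c("subject", "day")
    )
    agg$n_reaches[is.na(agg$n_reaches)] <- 0L
  }
  agg
}
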