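#' Tracked points expected in a pose table
#'
#' The four points labelled for this task: both forepaws, the nose, and the
#' reward pellet.
#'
#' @return Character vector of bodypart names.
#' @export
pose_bodyparts <- function() {
  c("left_paw", "right_paw", "nose", "pellet")
}

#' Construct a pose track
#'
#' A pose track holds one video's (or one concatenated session's) per-frame
#' coordinates and likelihoods for every tracked point, in image pixel
#' coordinates (origin top-left, y increasing downward), with 0-based frame
#' indices.
#'
#' @param data Data frame with a `frame` column (strictly increasing
#'   integers) and, for every bodypart `bp`, columns `bp_x`, `bp_y`,
#'   `bp_likelihood`.
#' @param fps Frames per second of the source video (default 240).
#' @param scorer Scorer string carried in the table header.
#' @param subject,day Optional identifiers carried as attributes.
#' @return A tibble of class `pose_track`.
#' @export
pose_track <- function(data, fps = 240, scorer = "reachlearn",
                       subject = NA_character_, day = NA_integer_) {
  data <- tibble::as_tibble(data)
  validate_pose_track(data)
  structure(
    data,
    fps = fps, scorer = scorer, subject = subject, day = as.integer(day),
    class = c("pose_track", class(tibble::tibble()))
  )
}

validate_pose_track <- function(data) {
  if (!"frame" %in% names(data)) {
    abort("pose track must have a `frame` column")
  }
  if (nrow(data) > 1 && any(diff(data$frame) <= 0)) {
    bad <- which(diff(data$frame) <= 0)[1] + 1L
    abort(sprintf("frame index not strictly increasing at row %d", bad))
  }
  bps <- track_bodyparts(data)
  if (length(bps) == 0) {
    abort("pose track has no `<bodypart>_{x,y,likelihood}` column triplets")
  }
  for (bp in bps) {
    lik <- data[[paste0(bp, "_likelihood")]]
    bad <- which(!is.na(lik) & (lik < 0 | lik > 1))
    if (length(bad) > 0) {
      abort(sprintf("likelihood outside [0, 1] for point '%s' at row %d", bp, bad[1]))
    }
  }
  invisible(data)
}

track_bodyparts <- function(data) {
  xs <- grep("_x$", names(data), value = TRUE)
  bps <- sub("_x$", "", xs)
  keep <- vapply(bps, function(bp) {
    all(paste0(bp, c("_y", "_likelihood")) %in% names(data))
  }, logical(1))
  bps[keep]
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf(
    "<pose_track> %d frames, %d points (%s), %g fps\n",
    nrow(x), length(track_bodyparts(x)),
    paste(track_bodyparts(x), collapse = ", "), attr(x, "fps")
  ))
  NextMethod()
}

#' Read a pose table in the DeepLabCut CSV dialect
#'
#' The dialect has three stacked header rows (scorer / bodyparts / coords,
#' with coords in x, y, likelihood) over data rows whose first column is the
#' integer frame index.
#'
#' @param path Path to a CSV file.
#' @param fps Frames per second recorded in the returned track.
#' @return A [pose_track()].
#' @export
read_pose_table <- function(path, fps = 240) {
  if (!file.exists(path)) abort(sprintf("pose table not found: %s", path))
  hdr <- readLines(path, n = 3)
  if (length(hdr) < 3) abort(sprintf("%s: expected 3 header rows, found %d", path, length(hdr)))
  rows <- lapply(hdr, function(l) strsplit(l, ",", fixed = TRUE)[[1]])
  labels <- vapply(rows, `[`, character(1), 1)
  expected <- c("scorer", "bodyparts", "coords")
  if (!identical(labels, expected)) {
    abort(sprintf(
      "%s: header row labels are (%s); expected (scorer, bodyparts, coords)",
      path, paste(labels, collapse = ", ")
    ))
  }
  scorer <- rows[[1]][2] %||% "unknown"
  bps <- rows[[2]][-1]
  coords <- rows[[3]][-1]
  bad_coord <- setdiff(unique(coords), c("x", "y", "likelihood"))
  if (length(bad_coord) > 0) {
    abort(sprintf("%s: unknown coord name '%s' in header row 3", path, bad_coord[1]))
  }
  if (length(bps) != length(coords)) {
    abort(sprintf("%s: bodyparts/coords header rows differ in length", path))
  }
  dat <- readr::read_csv(
    path,
    skip = 3, col_names = FALSE, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_double())
  )
  if (ncol(dat) > 0 && ncol(dat) != length(bps) + 1) {
    abort(sprintf(
      "%s: %d data columns but %d header columns", path, ncol(dat), length(bps) + 1
    ))
  }
  if (nrow(dat) == 0) {
    cols <- c("frame", paste(bps, coords, sep = "_"))
    out <- tibble::as_tibble(setNames(rep(list(numeric(0)), length(cols)), cols))
    out$frame <- integer(0)
    return(pose_track(out, fps = fps, scorer = scorer))
  }
  names(dat) <- c("frame", paste(bps, coords, sep = "_"))
  dat$frame <- as.integer(dat$frame)
  pose_track(dat, fps = fps, scorer = scorer)
}

#' Write a pose table in the DeepLabCut CSV dialect
#'
#' Emits the three stacked header rows followed by one row per frame. Output
#' is deterministic: two writes of the same track are byte-identical, and a
#' write/read round trip preserves coordinates to better than 1e-9 relative
#' error.
#'
#' @param track A [pose_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(track, path) {
  stopifnot(inherits(track, "pose_track"))
  bps <- track_bodyparts(track)
  scorer <- attr(track, "scorer") %||% "reachlearn"
  h1 <- paste(c("scorer", rep(scorer, 3 * length(bps))), collapse = ",")
  h2 <- paste(c("bodyparts", rep(bps, each = 3)), collapse = ",")
  h3 <- paste(c("coords", rep(c("x", "y", "likelihood"), length(bps))), collapse = ",")
  cols <- as.vector(t(outer(bps, c("_x", "_y", "_likelihood"), paste0)))
  body <- character(0)
  if (nrow(track) > 0) {
    num <- vapply(cols, function(cl) sprintf("%.12g", track[[cl]]), character(nrow(track)))
    num <- matrix(num, nrow = nrow(track))
    body <- paste(
      sprintf("%d", track$frame),
      apply(num, 1, paste, collapse = ","),
      sep = ","
    )
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(h1, h2, h3, body), con, sep = "\n")
  invisible(path)
}

#' Rectangular tracking bounds
#'
#' Axis-aligned pixel rectangle covering the region outside the slit where
#' reaches take place; points on the boundary count as inside.
#'
#' @param x_min,x_max,y_min,y_max Rectangle edges in pixels.
#' @return An object of class `tracking_bounds`.
#' @export
tracking_bounds <- function(x_min, x_max, y_min, y_max) {
  if (!(x_min < x_max)) abort("tracking bounds need x_min < x_max")
  if (!(y_min < y_max)) abort("tracking bounds need y_min < y_max")
  structure(
    list(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max),
    class = "tracking_bounds"
  )
}

#' @export
print.tracking_bounds <- function(x, ...) {
  cat(sprintf(
    "<tracking_bounds> x in [%g, %g], y in [%g, %g]\n",
    x$x_min, x$x_max, x$y_min, x$y_max
  ))
  invisible(x)
}

in_bounds <- function(x, y, bounds) {
  x >= bounds$x_min & x <= bounds$x_max & y >= bounds$y_min & y <= bounds$y_max
}

#' Filter one tracked point by likelihood and tracking bounds
#'
#' Retains exactly the samples with likelihood >= `p_cutoff` (the boundary
#' value is retained) whose position lies inside `bounds` (edges inclusive),
#' in frame order with original frame indices preserved. Filtering an
#' already-filtered track with the same parameters is the identity.
#'
#' @param track A [pose_track()], or the result of a previous `filter_track()`
#'   call.
#' @param point Bodypart to extract, e.g. `"left_paw"`. Ignored when `track`
#'   is already filtered.
#' @param p_cutoff Likelihood cutoff in \[0, 1\] (default 0.85, the value used
#'   for high-confidence trajectory analysis).
#' @param bounds A [tracking_bounds()].
#' @return A tibble of class `filtered_track` with columns `frame`, `x`, `y`,
#'   `likelihood` and attributes recording the point, cutoff and bounds used.
#' @export
filter_track <- function(track, point, p_cutoff = 0.85, bounds) {
  stopifnot(inherits(bounds, "tracking_bounds"))
  if (p_cutoff < 0 || p_cutoff > 1) abort("p_cutoff must lie in [0, 1]")
  if (inherits(track, "filtered_track")) {
    dat <- tibble::as_tibble(track)
    point <- attr(track, "point")
  } else {
    stopifnot(inherits(track, "pose_track"))
    if (!point %in% track_bodyparts(track)) {
      abort(sprintf(
        "unknown point '%s'; track has: %s",
        point, paste(track_bodyparts(track), collapse = ", ")
      ))
    }
    dat <- tibble::tibble(
      frame = track$frame,
      x = track[[paste0(point, "_x")]],
      y = track[[paste0(point, "_y")]],
      likelihood = track[[paste0(point, "_likelihood")]]
    )
  }
  keep <- !is.na(dat$likelihood) & dat$likelihood >= p_cutoff &
    in_bounds(dat$x, dat$y, bounds)
  out <- dat[keep, , drop = FALSE]
  structure(
    out,
    point = point, p_cutoff = p_cutoff, bounds = bounds,
    fps = attr(track, "fps"),
    class = c("filtered_track", class(tibble::tibble()))
  )
}
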