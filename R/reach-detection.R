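#' Reach-detection parameters
#'
#' Parameters of the directional-vector consensus detector: a candidate reach
#' start needs `window` consecutive step vectors among adjacent retained
#' samples of which at least `consensus` point toward the pellet; retraction
#' onset is found symmetrically with the opposite predicate, and candidate
#' reaches shorter than `min_points` samples are discarded.
#'
#' @param pellet Numeric length-2 pixel coordinate of the pellet used as the
#'   directional reference for the trial.
#' @param min_points Minimum number of samples in a reach (default 6).
#' @param window Number of consecutive step vectors tested (default 5).
#' @param consensus Minimum number of agreeing vectors in the window
#'   (default 4).
#' @param max_gap Maximum frame gap between consecutive retained samples for
#'   them to count as adjacent (default 5 frames, about 21 ms at 240 fps);
#'   larger gaps break a candidate window so reaches are not stitched across
#'   long occlusions.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(pellet, min_points = 6L, window = 5L,
                             consensus = 4L, max_gap = 5L) {
  if (length(pellet) != 2 || !all(is.finite(pellet))) {
    abort("pellet must be a finite (x, y) pixel pair")
  }
  if (consensus < 1 || consensus > window) {
    abort("need 1 <= consensus <= window")
  }
  if (min_points < window + 1) {
    abort("need min_points >= window + 1")
  }
  structure(
    list(
      pellet = as.numeric(pellet), min_points = as.integer(min_points),
      window = as.integer(window), consensus = as.integer(consensus),
      max_gap = as.integer(max_gap)
    ),
    class = "detection_params"
  )
}

#' Does a step move toward the pellet?
#'
#' TRUE iff the Euclidean distance to the pellet strictly decreases from
#' `p_from` to `p_to`. A zero-length step (and any step that leaves the
#' distance unchanged) is toward neither direction.
#'
#' @param p_from,p_to Numeric (x, y) pairs, or two-column matrices for a
#'   vectorised call.
#' @param pellet Numeric (x, y) pellet reference.
#' @return Logical.
#' @export
step_toward_pellet <- function(p_from, p_to, pellet) {
  p_from <- matrix(as.numeric(p_from), ncol = 2)
  p_to <- matrix(as.numeric(p_to), ncol = 2)
  d_from <- sqrt((p_from[, 1] - pellet[1])^2 + (p_from[, 2] - pellet[2])^2)
  d_to <- sqrt((p_to[, 1] - pellet[1])^2 + (p_to[, 2] - pellet[2])^2)
  d_to < d_from
}

#' Detect reaches in a filtered paw track
#'
#' Scans the retained samples in frame order. The earliest sample whose next
#' `window` step vectors (over pairwise-adjacent samples, frame gap <=
#' `max_gap`) reach directional consensus toward the pellet marks a reach
#' start; the earliest subsequent sample whose window reaches consensus in
#' the opposite direction (distance to pellet strictly increasing) marks the
#' retraction onset, which is the reach endpoint. Scanning then resumes after
#' the endpoint, alternating direction until the track is exhausted.
#' Candidate reaches with fewer than `min_points` samples are discarded. The
#' reach's point sequence runs from start to retraction onset inclusive; the
#' retraction phase itself is not part of the reach.
#'
#' @param track A [filter_track()] result (columns `frame`, `x`, `y`).
#' @param params A [detection_params()].
#' @return Tibble with one row per reach: `ordinal`, `start_frame`,
#'   `end_frame`, `n_points`, `start_idx`, `end_idx` (row indices into
#'   `track`) and a `points` list-column of `frame, x, y` tibbles. A track
#'   shorter than `min_points` yields zero rows.
#' @export
find_reaches <- function(track, params) {
  stopifnot(inherits(params, "detection_params"))
  dat <- tibble::as_tibble(track)
  n <- nrow(dat)
  empty <- tibble::tibble(
    ordinal = integer(0), start_frame = integer(0), end_frame = integer(0),
    n_points = integer(0), start_idx = integer(0), end_idx = integer(0),
    points = list()
  )
  if (n < params$min_points) return(empty)
  W <- params$window
  px <- params$pellet[1]
  py <- params$pellet[2]
  d <- sqrt((dat$x - px)^2 + (dat$y - py)^2)
  toward <- d[-1] < d[-n]
  away <- d[-1] > d[-n]
  adj <- diff(dat$frame) <= params$max_gap
  # window starting at sample i uses vectors i .. i+W-1; valid while i+W <= n
  m <- n - W
  if (m < 1) return(empty)
  cs_t <- c(0, cumsum(toward))
  cs_a <- c(0, cumsum(away))
  cs_bad <- c(0, cumsum(!adj))
  i_seq <- seq_len(m)
  win_adj <- (cs_bad[i_seq + W] - cs_bad[i_seq]) == 0
  start_ok <- win_adj & (cs_t[i_seq + W] - cs_t[i_seq]) >= params$consensus
  end_ok <- win_adj & (cs_a[i_seq + W] - cs_a[i_seq]) >= params$consensus
  starts <- integer(0)
  ends <- integer(0)
  i <- 1L
  repeat {
    if (i > m) break
    rel <- which(start_ok[i:m])
    if (length(rel) == 0) break
    s <- i + rel[1] - 1L
    if (s + 1L > m) break
    rel <- which(end_ok[(s + 1L):m])
    if (length(rel) == 0) break
    e <- s + rel[1]
    if (e - s + 1L >= params$min_points) {
      starts <- c(starts, s)
      ends <- c(ends, e)
    }
    i <- e + 1L
  }
  if (length(starts) == 0) return(empty)
  tibble::tibble(
    ordinal = seq_along(starts),
    start_frame = dat$frame[starts],
    end_frame = dat$frame[ends],
    n_points = ends - starts + 1L,
    start_idx = starts,
    end_idx = ends,
    points = purrr::map2(starts, ends, function(s, e) dat[s:e, c("frame", "x", "y")])
  )
}

#' Assign detected reaches to trial windows
#'
#' Each reach is assigned to the unique trial window containing its start
#' frame. Reaches starting outside every window are kept in an
#' `"unassigned"` attribute; trials with no assigned reach are flagged
#' `no_try`.
#'
#' @param reaches Tibble from [find_reaches()] (needs `start_frame`).
#' @param trial_windows Tibble with columns `trial`, `start_frame`,
#'   `end_frame`; windows must not overlap.
#' @return Tibble with one row per trial: `trial`, `start_frame`,
#'   `end_frame`, `n_reaches`, `no_try`, and a `reaches` list-column of the
#'   assigned reach rows (with a within-trial `ordinal`).
#' @export
assign_reaches_to_trials <- function(reaches, trial_windows) {
  tw <- dplyr::arrange(tibble::as_tibble(trial_windows), .data$start_frame)
  if (nrow(tw) > 1 && any(tw$start_frame[-1] <= tw$end_frame[-nrow(tw)])) {
    abort("trial windows overlap")
  }
  if (any(tw$end_frame < tw$start_frame)) abort("trial window with end < start")
  idx <- findInterval(reaches$start_frame, tw$start_frame)
  inside <- idx >= 1 & idx <= nrow(tw) &
    reaches$start_frame <= tw$end_frame[pmax(idx, 1)]
  assigned <- reaches[inside, , drop = FALSE]
  assigned$trial <- tw$trial[idx[inside]]
  assigned <- dplyr::arrange(assigned, .data$trial, .data$start_frame)
  assigned <- dplyr::mutate(
    dplyr::group_by(assigned, .data$trial),
    ordinal = dplyr::row_number()
  )
  assigned <- dplyr::ungroup(assigned)
  nested <- tidyr::nest(assigned, reaches = -"trial")
  out <- dplyr::left_join(tw, nested, by = "trial")
  out$n_reaches <- vapply(
    out$reaches, function(r) if (is.null(r)) 0L else nrow(r), integer(1)
  )
  out$no_try <- out$n_reaches == 0L
  out$reaches <- purrr::map(out$reaches, function(r) {
    if (is.null(r)) tibble::tibble() else r
  })
  out <- out[, c(
    "trial", "start_frame", "end_frame", "n_reaches", "no_try", "reaches"
  )]
  attr(out, "unassigned") <- reaches[!inside, , drop = FALSE]
  out
}
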