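# Independent brute-force oracles and random fixture generators. These are
# deliberately naive (explicit loops, re-derived formulas) so they share no
# code path with the package implementation.

# Exhaustive reach detector: tests every index as a candidate window start,
# recomputing both distances per step, and walks the alternating
# start/end/resume procedure one index at a time.
oracle_find_reaches <- function(track, params) {
  n <- nrow(track)
  W <- params$window
  dist_to <- function(i) {
    sqrt((track$x[i] - params$pellet[1])^2 + (track$y[i] - params$pellet[2])^2)
  }
  win_ok <- function(i, dir) {
    if (i + W > n) return(FALSE)
    votes <- 0
    for (k in i:(i + W - 1)) {
      if (track$frame[k + 1] - track$frame[k] > params$max_gap) return(FALSE)
      d1 <- dist_to(k)
      d2 <- dist_to(k + 1)
      if (dir == "toward" && d2 < d1) votes <- votes + 1
      if (dir == "away" && d2 > d1) votes <- votes + 1
    }
    votes >= params$consensus
  }
  starts <- integer(0)
  ends <- integer(0)
  i <- 1
  while (i <= n) {
    s <- NA
    for (j in i:n) {
      if (win_ok(j, "toward")) {
        s <- j
        break
      }
    }
    if (is.na(s) || s + 1 > n) break
    e <- NA
    for (j in (s + 1):n) {
      if (win_ok(j, "away")) {
        e <- j
        break
      }
    }
    if (is.na(e)) break
    if (e - s + 1 >= params$min_points) {
      starts <- c(starts, s)
      ends <- c(ends, e)
    }
    i <- e + 1
  }
  data.frame(start_idx = starts, end_idx = ends)
}

# Random filtered-track generator mixing drift segments (toward or away from
# the pellet), stationary dwell, and frame gaps, to exercise the detector on
# both reach-like and degenerate structure.
random_filtered_track <- function(n, pellet = c(50, 50), gap_prob = 0.1,
                                  max_gap_step = 8) {
  x <- numeric(n)
  y <- numeric(n)
  x[1] <- runif(1, 0, 100)
  y[1] <- runif(1, 0, 100)
  mode <- sample(c("toward", "away", "wander", "still"), 1)
  for (i in 2:n) {
    if (runif(1) < 0.15) {
      mode <- sample(c("toward", "away", "wander", "still"), 1)
    }
    dir <- c(pellet[1] - x[i - 1], pellet[2] - y[i - 1])
    nrm <- sqrt(sum(dir^2))
    if (nrm < 1e-9) dir <- c(1, 0) else dir <- dir / nrm
    step <- switch(mode,
      toward = dir * runif(1, 0.5, 3) + rnorm(2, 0, 0.4),
      away = -dir * runif(1, 0.5, 3) + rnorm(2, 0, 0.4),
      wander = rnorm(2, 0, 2),
      still = c(0, 0)
    )
    x[i] <- x[i - 1] + step[1]
    y[i] <- y[i - 1] + step[2]
  }
  gaps <- ifelse(runif(n - 1) < gap_prob, sample(2:max_gap_step, n - 1, TRUE), 1)
  tibble::tibble(frame = as.integer(cumsum(c(0, gaps))), x = x, y = y)
}

# Brute-force kinematics recomputation.
oracle_path_length <- function(reach) {
  tot <- 0
  for (i in 2:nrow(reach)) {
    tot <- tot + sqrt((reach$x[i] - reach$x[i - 1])^2 +
                        (reach$y[i] - reach$y[i - 1])^2)
  }
  tot
}

oracle_delta_y <- function(reach) {
  hi <- -Inf
  lo <- Inf
  for (i in seq_len(nrow(reach))) {
    if (reach$y[i] > hi) hi <- reach$y[i]
    if (reach$y[i] < lo) lo <- reach$y[i]
  }
  hi - lo
}

oracle_delta_x <- function(reach, slit_x, toward_sign) {
  best <- 0
  for (i in seq_len(nrow(reach))) {
    v <- toward_sign * (reach$x[i] - slit_x)
    if (v > best) best <- v
  }
  best
}

random_reach <- function(n = NULL) {
  n <- if (is.null(n)) sample(2:40, 1) else n
  tibble::tibble(
    frame = seq_len(n) - 1L,
    x = runif(n, 0, 640),
    y = runif(n, 0, 480)
  )
}

# Small random pose table for I/O properties.
random_pose_table <- function(n = 20) {
  dat <- tibble::tibble(frame = seq_len(n) - 1L)
  for (bp in pose_bodyparts()) {
    dat[[paste0(bp, "_x")]] <- runif(n, 0, 640)
    dat[[paste0(bp, "_y")]] <- runif(n, 0, 480)
    dat[[paste0(bp, "_likelihood")]] <- runif(n)
  }
  pose_track(dat, fps = 240)
}

# Compact noiseless cohort configuration used across recovery tests.
noiseless_groups <- function(n_subjects = 3) {
  g <- default_sim_groups(n_subjects)
  g$noise_sigma_d1 <- 0
  g$noise_sigma_d8 <- 0
  g$vspread_d1 <- 0
  g$vspread_d8 <- 0
  g
}
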