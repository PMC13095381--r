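#' Reach outcome labels
#'
#' The outcome taxonomy used for scoring: a retrieval brought back through
#' the slit (`success`), a targeted reach with no pellet contact
#' (`complete_miss`), contact without retrieval (`contact_miss`), a reach
#' made while no pellet was present (`vain`), and a residual `other`
#' category. All labels except `vain` are targeted reaches.
#'
#' @return Character vector of the five labels.
#' @export
reach_labels <- function() {
  c("success", "complete_miss", "contact_miss", "vain", "other")
}

# Apex offset (relative to the pellet) of a simulated reach, given its
# outcome: retrievals and contact misses touch the pellet, complete misses
# overshoot it in x with a lateral aiming error, "other" reaches sit between.
reach_apex_offset <- function(config, day, group, outcome, lateral_sign) {
  ov <- sim_curve(config, group, "overshoot", day)
  switch(outcome,
    success = ,
    contact_miss = ,
    vain = c(0, 0),
    complete_miss = c(ov, lateral_sign * config$miss_offset_px),
    other = c(ov / 2, lateral_sign * config$miss_offset_px * 0.6),
    abort(sprintf("unknown outcome label '%s'", outcome))
  )
}

#' Simulate one reach trajectory
#'
#' Generates the paw point sequence of a single reach as an outward limb
#' from just beyond the slit plane to an outcome-dependent apex, followed by
#' a mirrored retraction, with Gaussian horizontal jitter (sd = the day's
#' trajectory noise) and vertical jitter (sd = the day's vertical spread).
#'
#' The noiseless skeleton has a unimodal paw-pellet distance profile:
#' distance to the pellet decreases strictly along the outward limb and
#' increases strictly along the retraction, with the apex as the point of
#' closest approach. Retrievals and contact misses touch the pellet at the
#' apex; complete misses sweep an arc whose apex overshoots the pellet in x
#' by the day's overshoot value with a lateral aiming error, so the paw
#' passes the target without contact. Draws from the current RNG state; set
#' a seed for reproducibility.
#'
#' @param config A [sim_config()].
#' @param day Day in `1:config$days`.
#' @param group Group label in `config$groups$group`.
#' @param outcome One of [reach_labels()].
#' @param start_frame Frame index of the first sample.
#' @return Tibble with columns `frame`, `x`, `y`, `likelihood`, one row per
#'   sample (`reach_points_out + reach_points_back` rows). Per-frame dropout
#'   replaces the likelihood with a value below 0.05.
#' @export
simulate_reach_trajectory <- function(config, day, group, outcome,
                                      start_frame = 0L) {
  if (!outcome %in% reach_labels()) {
    abort(sprintf("unknown outcome label '%s'", outcome))
  }
  if (day < 1 || day > config$days) {
    abort(sprintf("day must lie in [1, %d]", config$days))
  }
  lateral_sign <- sample(c(-1, 1), 1)
  apex_off <- reach_apex_offset(config, day, group, outcome, lateral_sign)
  pellet <- config$pellet_xy
  start <- c(config$slit_x + 2, pellet[2])
  n_out <- config$reach_points_out
  n_back <- config$reach_points_back
  t_out <- seq(0, 1, length.out = n_out)
  t_back <- 1 - seq_len(n_back) / n_back
  tt <- c(t_out, t_back)
  n <- length(tt)
  # polar construction around the pellet: radius shrinks linearly from the
  # start distance to the apex distance while the bearing sweeps from the
  # slit direction to the apex direction, so every outward step strictly
  # approaches the pellet and every retraction step strictly recedes
  d0 <- sqrt(sum((start - pellet)^2))
  d_apex <- sqrt(sum(apex_off^2))
  th0 <- atan2(start[2] - pellet[2], start[1] - pellet[1])
  # touching reaches head straight for the pellet; misses sweep an arc
  th_apex <- if (d_apex > 0) atan2(apex_off[2], apex_off[1]) else th0
  dth <- (th_apex - th0) %% (2 * pi)
  if (dth > pi) dth <- dth - 2 * pi
  d_t <- d0 + tt * (d_apex - d0)
  th_t <- th0 + tt * dth
  ns <- sim_curve(config, group, "noise_sigma", day)
  vs <- sim_curve(config, group, "vspread", day)
  x <- pellet[1] + d_t * cos(th_t) + rnorm(n, 0, ns)
  y <- pellet[2] + d_t * sin(th_t) + rnorm(n, 0, vs)
  lik <- runif(n, 0.9, 1)
  drop <- runif(n) < config$dropout_prob
  lik[drop] <- runif(sum(drop), 0, 0.049)
  tibble::tibble(
    frame = as.integer(start_frame + seq_len(n) - 1L),
    x = x, y = y, likelihood = lik
  )
}

# Number of samples in every simulated reach.
reach_sample_count <- function(config) {
  config$reach_points_out + config$reach_points_back
}

# Vectorised outcome/timing engine shared by simulate_trial() and
# simulate_cohort(). `grid` has one row per trial (subject, group, day,
# trial). Returns list(trials, reaches) with frame indices relative to the
# trial window start.
simulate_outcomes <- function(config, grid) {
  n <- nrow(grid)
  fr <- trial_frames(config)
  n_pts <- reach_sample_count(config)
  # cap events per trial so slots stay wide enough for disjoint reaches
  e_cap <- max(1L, as.integer(fr %/% (4L * n_pts)) - 1L)

  no_try <- runif(n) < config$no_try_rate
  k_planned <- pmin(1L + rpois(n, config$attempts_lambda), config$max_attempts)
  k_planned[no_try] <- 0L
  q <- numeric(n)
  for (g in unique(grid$group)) {
    idx <- grid$group == g
    q[idx] <- sim_curve(config, g, "success", grid$day[idx])
  }

  att <- tibble::tibble(
    row = rep(seq_len(n), k_planned),
    ordinal = sequence(k_planned)
  )
  att$succ <- runif(nrow(att)) < q[att$row]
  # a retrieval removes the pellet: attempts after the first success are
  # not targeted attempts and are dropped here (vain reaches added below)
  prior_succ <- unlist(lapply(split(att$succ, att$row), function(s) {
    cumsum(c(FALSE, s[-length(s)]))
  }), use.names = FALSE)
  if (nrow(att) > 0) att <- att[prior_succ == 0, , drop = FALSE]
  fail_labels <- names(config$failure_mix)
  att$label <- character(nrow(att))
  att$label[att$succ] <- "success"
  n_fail <- sum(!att$succ)
  att$label[!att$succ] <- fail_labels[
    sample.int(length(fail_labels), n_fail, replace = TRUE,
               prob = config$failure_mix)
  ]

  # vain reaches: post-removal attempts in a fraction of retrieval trials
  succ_rows <- att$row[att$succ]
  vain_trial <- succ_rows[runif(length(succ_rows)) < config$vain_rate]
  n_vain <- 1L + rpois(length(vain_trial), 0.3)
  last_ord <- vapply(
    split(att$ordinal, att$row), max, numeric(1)
  )[as.character(vain_trial)]
  vain <- tibble::tibble(
    row = rep(vain_trial, n_vain),
    ordinal = unlist(purrr::map2(last_ord, n_vain, function(l, k) l + seq_len(k)),
                     use.names = FALSE),
    succ = FALSE,
    label = "vain"
  )
  ev <- dplyr::arrange(dplyr::bind_rows(att, vain), .data$row, .data$ordinal)
  # re-rank ordinals and drop events beyond the per-trial cap
  ev <- dplyr::mutate(
    dplyr::group_by(ev, .data$row),
    ordinal = dplyr::row_number(), n_events = dplyr::n()
  )
  ev <- dplyr::ungroup(ev)
  ev <- ev[ev$ordinal <= e_cap, , drop = FALSE]
  ev$n_events <- pmin(ev$n_events, e_cap)

  # slot placement: trial window split into n_events + 1 slots, each reach
  # jittered inside its slot; slots are wide enough that reaches never touch
  slot <- fr / (ev$n_events + 1)
  ev$start_frame <- as.integer(floor(((ev$ordinal - 1) + 0.15 + 0.7 * runif(nrow(ev))) * slot))
  ev$end_frame <- ev$start_frame + n_pts - 1L

  trials <- grid
  trials$no_try <- tabulate(ev$row, nbins = n) == 0L
  trials$n_frames <- fr
  succ_end <- rep(NA_integer_, n)
  se <- ev[ev$succ, c("row", "end_frame")]
  succ_end[se$row] <- se$end_frame
  trials$pellet_start <- 0L
  trials$pellet_end <- ifelse(is.na(succ_end), fr - 1L, succ_end)

  reaches <- tibble::tibble(
    subject = grid$subject[ev$row], group = grid$group[ev$row],
    day = grid$day[ev$row], trial = grid$trial[ev$row],
    ordinal = ev$ordinal, label = ev$label,
    start_frame = ev$start_frame, end_frame = ev$end_frame
  )
  list(trials = trials, reaches = reaches)
}

#' Simulate one trial
#'
#' Draws a single trial's ground truth: whether the mouse tried at all, its
#' attempt sequence (at most one success, since retrieval removes the
#' pellet), any post-removal vain reaches, and reach placement within the
#' access window. Frame indices are relative to the trial window.
#'
#' @inheritParams simulate_reach_trajectory
#' @param subject,trial Identifiers carried into the output.
#' @return List with `reaches` (tibble: `ordinal`, `label`, `start_frame`,
#'   `end_frame`), `no_try`, `pellet_interval` (`c(start, end)` frames during
#'   which the pellet is present) and `n_frames`
#'   (`round(access_window * fps)`).
#' @export
simulate_trial <- function(config, day, group, subject = "s01", trial = 1L) {
  if (!group %in% config$groups$group) abort(sprintf("unknown group '%s'", group))
  grid <- tibble::tibble(subject = subject, group = group,
                         day = as.integer(day), trial = as.integer(trial))
  out <- simulate_outcomes(config, grid)
  list(
    reaches = out$reaches[, c("ordinal", "label", "start_frame", "end_frame")],
    no_try = out$trials$no_try[1],
    pellet_interval = c(out$trials$pellet_start[1], out$trials$pellet_end[1]),
    n_frames = out$trials$n_frames[1]
  )
}

#' Simulate a complete cohort
#'
#' Generates the full ground truth of a synthetic cohort — subject manifest,
#' per-trial records and labelled reach intervals — for every subject, day
#' and trial in the configuration. Pose tracks are not materialised here;
#' they are rendered deterministically per subject-day by
#' [simulate_session_poses()] (or all at once by [write_cohort()]), so large
#' cohorts can be analysed without holding every frame in memory.
#'
#' Frame indices in the returned tables are absolute within a subject-day:
#' trial `t` occupies frames `(t-1)*F .. t*F - 1` with
#' `F = round(access_window * fps)`.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; when given, [write_cohort()] is called and
#'   pose tables, manifest and ground truth are written there.
#' @return An object of class `reach_cohort`: list with `manifest` (subject,
#'   group, genotype, sex, condition), `trials` (subject, group, day, trial,
#'   no_try, pellet_start, pellet_end, window_start, window_end), `reaches`
#'   (subject, day, trial, ordinal, label, start_frame, end_frame) and
#'   `config`.
#' @export
simulate_cohort <- function(config, dir = NULL) {
  set.seed(config$seed)
  manifest <- dplyr::bind_rows(purrr::pmap(
    config$groups[, c("group", "genotype", "condition", "n_subjects")],
    function(group, genotype, condition, n_subjects) {
      tibble::tibble(
        subject = sprintf("%s%02d", group, seq_len(n_subjects)),
        group = group, genotype = genotype,
        sex = rep_len(c("f", "m"), n_subjects),
        condition = condition
      )
    }
  ))
  grid <- tidyr::crossing(
    manifest[, c("subject", "group")],
    day = seq_len(config$days),
    trial = seq_len(config$trials_per_day)
  )
  grid <- dplyr::arrange(grid, .data$subject, .data$day, .data$trial)
  out <- simulate_outcomes(config, grid)
  fr <- trial_frames(config)
  off <- (out$trials$trial - 1L) * fr
  trials <- dplyr::mutate(
    out$trials,
    window_start = off, window_end = off + fr - 1L,
    pellet_start = .data$pellet_start + off,
    pellet_end = .data$pellet_end + off
  )
  roff <- (out$reaches$trial - 1L) * fr
  reaches <- dplyr::mutate(
    out$reaches,
    start_frame = .data$start_frame + roff,
    end_frame = .data$end_frame + roff
  )
  cohort <- structure(
    list(manifest = manifest, trials = trials, reaches = reaches,
         config = config, pose_dir = NULL),
    class = "reach_cohort"
  )
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.reach_cohort <- function(x, ...) {
  cat(sprintf(
    "<reach_cohort> %d subjects (%s), %d days x %d trials, %d reaches\n",
    nrow(x$manifest),
    paste(sprintf("%s n=%d", x$config$groups$group, x$config$groups$n_subjects),
          collapse = ", "),
    x$config$days, x$config$trials_per_day, nrow(x$reaches)
  ))
  invisible(x)
}

#' Render the pose track of one subject-day
#'
#' Builds the full DeepLabCut-style frame sequence for one subject-day of a
#' simulated cohort: baseline frames with the paws inside the box (outside
#' the tracking bounds), reach trajectories overwriting the reaching paw at
#' the ground-truth intervals, a static pellet whose likelihood collapses
#' after retrieval, and per-frame occlusion dropout. Rendering is
#' deterministic given the cohort's configuration (a per-subject-day
#' sub-seed is derived from the cohort seed).
#'
#' @param cohort A [simulate_cohort()] result.
#' @param subject,day Which session to render.
#' @return A [pose_track()] with `config$trials_per_day *
#'   round(access_window * fps)` frames.
#' @export
simulate_session_poses <- function(cohort, subject, day) {
  config <- cohort$config
  man <- cohort$manifest[cohort$manifest$subject == subject, ]
  if (nrow(man) != 1) abort(sprintf("unknown subject '%s'", subject))
  set.seed(pose_subseed(config, subject, day))
  fr <- trial_frames(config)
  n <- fr * config$trials_per_day
  clip <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  box_x <- function() clip(rnorm(n, config$slit_x - 90, 15), 5, config$slit_x - 30)
  box_y <- function() clip(rnorm(n, 300, 25), 5, 475)

  paw <- config$paw
  other_paw <- setdiff(c("left_paw", "right_paw"), paw)
  dat <- tibble::tibble(frame = seq_len(n) - 1L)
  dat[[paste0(paw, "_x")]] <- box_x()
  dat[[paste0(paw, "_y")]] <- box_y()
  dat[[paste0(paw, "_likelihood")]] <- runif(n, 0.5, 0.99)
  dat[[paste0(other_paw, "_x")]] <- box_x()
  dat[[paste0(other_paw, "_y")]] <- box_y()
  dat[[paste0(other_paw, "_likelihood")]] <- runif(n, 0.5, 0.99)
  dat$nose_x <- clip(rnorm(n, config$slit_x - 40, 10), 5, config$slit_x - 5)
  dat$nose_y <- clip(rnorm(n, 220, 15), 5, 475)
  dat$nose_likelihood <- runif(n, 0.85, 1)

  trials <- cohort$trials[cohort$trials$subject == subject &
                            cohort$trials$day == day, ]
  present <- rep(FALSE, n)
  for (i in seq_len(nrow(trials))) {
    present[(trials$pellet_start[i]:trials$pellet_end[i]) + 1L] <- TRUE
  }
  dat$pellet_x <- config$pellet_xy[1]
  dat$pellet_y <- config$pellet_xy[2]
  dat$pellet_likelihood <- ifelse(present, runif(n, 0.9, 1), runif(n, 0, 0.04))

  gt <- cohort$reaches[cohort$reaches$subject == subject &
                         cohort$reaches$day == day, ]
  gt <- dplyr::arrange(gt, .data$start_frame)
  for (i in seq_len(nrow(gt))) {
    traj <- simulate_reach_trajectory(
      config, day, man$group, gt$label[i], start_frame = gt$start_frame[i]
    )
    rows <- gt$start_frame[i]:gt$end_frame[i] + 1L
    dat[[paste0(paw, "_x")]][rows] <- traj$x
    dat[[paste0(paw, "_y")]][rows] <- traj$y
    dat[[paste0(paw, "_likelihood")]][rows] <- traj$likelihood
  }

  if (config$dropout_prob > 0) {
    for (bp in pose_bodyparts()) {
      drop <- runif(n) < config$dropout_prob
      col <- paste0(bp, "_likelihood")
      dat[[col]][drop] <- runif(sum(drop), 0, 0.049)
    }
  }
  pose_track(dat, fps = config$fps, subject = subject, day = day)
}

#' Trial windows of a simulated subject-day
#'
#' @param config A [sim_config()].
#' @return Tibble `trial`, `start_frame`, `end_frame` covering one session.
#' @export
sim_trial_windows <- function(config) {
  fr <- trial_frames(config)
  t <- seq_len(config$trials_per_day)
  tibble::tibble(trial = t, start_frame = (t - 1L) * fr, end_frame = t * fr - 1L)
}

#' Write a simulated cohort to disk
#'
#' Emits one pose table per subject-day in the DeepLabCut CSV dialect
#' (`poses/<subject>_day<dd>.csv`), a tab-separated `manifest.tsv` (subject,
#' group, genotype, sex, condition), `trials.tsv`, and a tab-separated
#' `ground_truth.tsv` with one row per reach (subject, day, trial, ordinal,
#' start_frame, end_frame, label, no_try) plus one row per no-try trial.
#' Re-running with the same configuration reproduces identical files.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) {
    abort(sprintf("cannot write cohort to '%s'", dir))
  }
  pose_dir <- file.path(dir, "poses")
  dir.create(pose_dir, showWarnings = FALSE)
  readr::write_tsv(cohort$manifest, file.path(dir, "manifest.tsv"), progress = FALSE)
  readr::write_tsv(cohort$trials, file.path(dir, "trials.tsv"), progress = FALSE)
  gt_reach <- dplyr::mutate(cohort$reaches, no_try = FALSE)
  gt_notry <- dplyr::transmute(
    cohort$trials[cohort$trials$no_try, ],
    subject = .data$subject, group = .data$group, day = .data$day,
    trial = .data$trial, ordinal = NA_integer_, label = NA_character_,
    start_frame = NA_integer_, end_frame = NA_integer_, no_try = TRUE
  )
  gt <- dplyr::arrange(dplyr::bind_rows(gt_reach, gt_notry),
                       .data$subject, .data$day, .data$trial)
  readr::write_tsv(gt, file.path(dir, "ground_truth.tsv"), progress = FALSE)
  for (s in cohort$manifest$subject) {
    for (d in seq_len(cohort$config$days)) {
      track <- simulate_session_poses(cohort, s, d)
      write_pose_table(track, file.path(pose_dir, sprintf("%s_day%02d.csv", s, d)))
    }
  }
  invisible(dir)
}
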