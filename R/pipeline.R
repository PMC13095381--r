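#' Run the full reach-analysis pipeline on a cohort
#'
#' Composes the analysis stages in order, per subject-day: render or read the
#' pose track, filter the reaching paw by likelihood and tracking bounds,
#' detect reaches by directional-vector consensus, assign them to trial
#' windows, compute per-reach kinematics, score outcomes, and assemble
#' learning curves. Outcome labels come from the cohort's ground-truth
#' annotations (`labels = "annotations"`) or from the geometric classifier
#' run on the detected reaches (`labels = "auto"`).
#'
#' The detection paw is the configured reaching paw by default; with
#' `paw = "auto"` each session uses whichever paw retains more in-bounds
#' high-likelihood samples.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param p_cutoff Likelihood cutoff (default 0.85).
#' @param params Optional [detection_params()]; defaults are built from the
#'   cohort configuration (pellet reference = configured pellet coordinate).
#' @param labels `"annotations"` or `"auto"`.
#' @param paw Reaching paw, or `"auto"`.
#' @param days Days to process (default all); restricting days speeds up
#'   kinematics-only analyses.
#' @return An object of class `reach_pipeline`: list with `detections`
#'   (per-reach detection + kinematics table), `kin_by_day` (subject-day
#'   aggregates), `summaries` (scored session summaries with all `pct_*`
#'   metrics, joined with the manifest), and the parameters used.
#' @export
run_reach_pipeline <- function(cohort, p_cutoff = 0.85, params = NULL,
                               labels = c("annotations", "auto"),
                               paw = NULL, days = NULL) {
  labels <- match.arg(labels)
  config <- cohort$config
  params <- params %||% detection_params(pellet = config$pellet_xy)
  paw <- paw %||% config$paw
  days <- days %||% seq_len(config$days)
  windows <- sim_trial_windows(config)

  det_list <- list()
  auto_list <- list()
  for (s in cohort$manifest$subject) {
    for (d in days) {
      track <- session_poses(cohort, s, d)
      ft <- session_paw_track(track, paw, p_cutoff, config$bounds)
      reaches <- find_reaches(ft, params)
      assigned <- assign_reaches_to_trials(reaches, windows)
      flat <- tidyr::unnest(
        assigned[assigned$n_reaches > 0, c("trial", "reaches")],
        "reaches"
      )
      if (nrow(flat) > 0) {
        flat$subject <- s
        flat$day <- d
        if (labels == "auto") {
          pellet <- tibble::tibble(
            frame = track$frame, x = track$pellet_x, y = track$pellet_y,
            likelihood = track$pellet_likelihood
          )
          flat$label <- purrr::map_chr(
            flat$points, auto_classify_reach, pellet_track = pellet,
            contact_radius_px = config$contact_radius_px, p_cutoff = p_cutoff
          )
          auto_list[[length(auto_list) + 1L]] <- flat
        }
        det_list[[length(det_list) + 1L]] <- flat
      }
    }
  }
  detections <- dplyr::bind_rows(det_list)
  if (nrow(detections) > 0) {
    detections <- reach_kinematics(
      detections, slit_x = config$slit_x, toward_sign = 1, fps = config$fps
    )
  }
  grid <- tidyr::crossing(subject = cohort$manifest$subject, day = days)
  kin_by_day <- if (nrow(detections) > 0) {
    aggregate_kinematics(detections, grid = grid)
  } else {
    tibble::tibble()
  }

  trials <- cohort$trials[cohort$trials$day %in% days, ]
  if (labels == "annotations") {
    scored <- cohort$reaches[cohort$reaches$day %in% days, ]
  } else {
    scored <- dplyr::bind_rows(auto_list)
    scored <- scored[, c("subject", "day", "trial", "ordinal", "label")]
    # trials where detection found no reach count as no-try for scoring
    found <- dplyr::distinct(scored, .data$subject, .data$day, .data$trial)
    found$has_reach <- TRUE
    trials <- dplyr::left_join(
      trials, found, by = c("subject", "day", "trial")
    )
    trials$no_try <- is.na(trials$has_reach)
    trials$has_reach <- NULL
  }
  summaries <- outcome_rates(summarize_sessions(scored, trials))
  summaries <- dplyr::left_join(summaries, cohort$manifest, by = "subject")

  structure(
    list(detections = detections, kin_by_day = kin_by_day,
         summaries = summaries, p_cutoff = p_cutoff, params = params,
         labels = labels, paw = paw, config = config),
    class = "reach_pipeline"
  )
}

# pose source: lazily simulated, or read back from a written cohort
session_poses <- function(cohort, subject, day) {
  if (is.null(cohort$pose_dir)) {
    simulate_session_poses(cohort, subject, day)
  } else {
    read_pose_table(
      file.path(cohort$pose_dir, sprintf("%s_day%02d.csv", subject, day)),
      fps = cohort$config$fps
    )
  }
}

# pick and filter the detection paw; paw = "auto" takes the paw with more
# retained in-bounds samples in this session
session_paw_track <- function(track, paw, p_cutoff, bounds) {
  if (identical(paw, "auto")) {
    cand <- lapply(c("left_paw", "right_paw"), function(p) {
      filter_track(track, p, p_cutoff, bounds)
    })
    cand[[which.max(vapply(cand, nrow, integer(1)))]]
  } else {
    filter_track(track, paw, p_cutoff, bounds)
  }
}

#' Read a cohort written by [write_cohort()]
#'
#' Restores the manifest, trial table and ground-truth reaches from disk;
#' pose tables are read lazily per subject-day by the pipeline.
#'
#' @param dir Directory produced by [write_cohort()].
#' @param config The [sim_config()] that generated the cohort (carried for
#'   trial geometry: fps, window length, bounds, pellet coordinate).
#' @return A `reach_cohort` whose pose source is the on-disk tables.
#' @export
read_cohort <- function(dir, config) {
  need <- file.path(dir, c("manifest.tsv", "trials.tsv", "ground_truth.tsv"))
  miss <- need[!file.exists(need)]
  if (length(miss) > 0) abort(sprintf("missing cohort input: %s", miss[1]))
  gt <- readr::read_tsv(need[3], show_col_types = FALSE, progress = FALSE)
  structure(
    list(
      manifest = readr::read_tsv(need[1], show_col_types = FALSE, progress = FALSE),
      trials = readr::read_tsv(need[2], show_col_types = FALSE, progress = FALSE),
      reaches = gt[!gt$no_try, setdiff(names(gt), "no_try")],
      config = config,
      pose_dir = file.path(dir, "poses")
    ),
    class = "reach_cohort"
  )
}

#' @export
print.reach_pipeline <- function(x, ...) {
  cat(sprintf(
    "<reach_pipeline> %d detected reaches, %d scored subject-days (labels: %s, p-cutoff %g)\n",
    nrow(x$detections), nrow(x$summaries), x$labels, x$p_cutoff
  ))
  invisible(x)
}

#' Extract learning curves from pipeline summaries
#'
#' @param summaries Summary table (e.g. `pipeline$summaries` or a
#'   kinematics aggregate joined with the manifest).
#' @param metric Column to use as the curve value.
#' @return Tibble `subject`, metadata columns, `day`, `value`, ready for
#'   [learning_index()], [day1_vs_day8_test()] and [longitudinal_model()].
#' @export
learning_curves <- function(summaries, metric) {
  if (!metric %in% names(summaries)) {
    abort(sprintf("metric column '%s' not found", metric))
  }
  meta <- intersect(c("genotype", "sex", "condition", "group"), names(summaries))
  out <- summaries[, c("subject", meta, "day", metric)]
  names(out)[ncol(out)] <- "value"
  out
}
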