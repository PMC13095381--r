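#' Summarise scored trials into per-subject-day session counts
#'
#' Tabulates the outcome taxonomy for every subject-day: trial counts
#' (total, no-try, attempted, successful, first-reach-successful) and reach
#' counts per label, with `n_targeted = n_total_reaches - n_vain`. A trial
#' is successful if it contains a success reach (at most one per trial,
#' since retrieval removes the pellet); it is a first-reach success if its
#' ordinal-1 reach is a success.
#'
#' @param reaches Tibble of labelled reaches with columns `subject`, `day`,
#'   `trial`, `ordinal`, `label` (labels from [reach_labels()]).
#' @param trials Tibble of trials with columns `subject`, `day`, `trial`,
#'   `no_try`; a no-try trial must have zero reaches. Extra columns are
#'   ignored (join group metadata onto the result instead).
#' @return Tibble with one row per subject-day and columns `n_trials`,
#'   `n_no_try`, `n_trials_attempted`, `n_success_trials`,
#'   `n_first_reach_success`, `n_success`, `n_complete_miss`,
#'   `n_contact_miss`, `n_other`, `n_vain`, `n_targeted`, `n_total_reaches`.
#' @export
summarize_sessions <- function(reaches, trials) {
  if (nrow(reaches) == 0) {
    reaches <- tibble::tibble(
      subject = character(0), day = integer(0), trial = integer(0),
      ordinal = integer(0), label = character(0)
    )
  }
  bad <- setdiff(unique(reaches$label), reach_labels())
  if (length(bad) > 0) {
    abort(sprintf("unknown reach label '%s'", bad[1]))
  }
  per_trial <- if (nrow(reaches) == 0) {
    tibble::tibble(
      subject = character(0), day = integer(0), trial = integer(0),
      n_reaches = integer(0), n_success_in_trial = integer(0),
      success = logical(0), first_reach_success = logical(0)
    )
  } else {
    dplyr::summarise(
      dplyr::group_by(reaches, .data$subject, .data$day, .data$trial),
      n_reaches = dplyr::n(),
      n_success_in_trial = sum(.data$label == "success"),
      success = .data$n_success_in_trial > 0,
      first_reach_success =
        any(.data$label[.data$ordinal == min(.data$ordinal)] == "success"),
      .groups = "drop"
    )
  }
  if (any(per_trial$n_success_in_trial > 1)) {
    abort("trial with more than one success reach: retrieval removes the pellet")
  }
  tr <- dplyr::left_join(
    tibble::as_tibble(trials)[, c("subject", "day", "trial", "no_try")],
    per_trial, by = c("subject", "day", "trial")
  )
  if (any(tr$no_try & !is.na(tr$n_reaches))) {
    abort("trial flagged no_try has reaches")
  }
  tr$success[is.na(tr$success)] <- FALSE
  tr$first_reach_success[is.na(tr$first_reach_success)] <- FALSE
  trial_side <- dplyr::summarise(
    dplyr::group_by(tr, .data$subject, .data$day),
    n_trials = dplyr::n(),
    n_no_try = sum(.data$no_try),
    n_trials_attempted = sum(!.data$no_try),
    n_success_trials = sum(.data$success),
    n_first_reach_success = sum(.data$first_reach_success),
    .groups = "drop"
  )
  reach_side <- dplyr::summarise(
    dplyr::group_by(reaches, .data$subject, .data$day),
    n_success = sum(.data$label == "success"),
    n_complete_miss = sum(.data$label == "complete_miss"),
    n_contact_miss = sum(.data$label == "contact_miss"),
    n_other = sum(.data$label == "other"),
    n_vain = sum(.data$label == "vain"),
    n_total_reaches = dplyr::n(),
    .groups = "drop"
  )
  out <- dplyr::left_join(trial_side, reach_side, by = c("subject", "day"))
  cnt <- c("n_success", "n_complete_miss", "n_contact_miss", "n_other",
           "n_vain", "n_total_reaches")
  for (cl in cnt) out[[cl]][is.na(out[[cl]])] <- 0L
  dplyr::mutate(out, n_targeted = .data$n_total_reaches - .data$n_vain)
}

#' Summarise one subject-day
#'
#' Single-session variant of [summarize_sessions()]; errors if the input
#' mixes subject-days.
#'
#' @inheritParams summarize_sessions
#' @return One-row tibble (see [summarize_sessions()]).
#' @export
summarize_session <- function(reaches, trials) {
  key <- dplyr::distinct(tibble::as_tibble(trials), .data$subject, .data$day)
  if (nrow(key) != 1) abort("summarize_session() needs a single subject-day")
  summarize_sessions(reaches, trials)
}

pct_or_na <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)

#' Percentage of successful trials
#'
#' `100 * n_success_trials / n_trials_attempted`; trials with no reach
#' attempts are excluded from the denominator, and a subject-day with no
#' attempted trials yields a missing value.
#'
#' @param summary Output of [summarize_sessions()].
#' @return `summary` with an added `pct_success_by_trial` column.
#' @export
success_rate_by_trial <- function(summary) {
  dplyr::mutate(summary, pct_success_by_trial =
    pct_or_na(.data$n_success_trials, .data$n_trials_attempted))
}

#' Percentage of successful reaches out of targeted reaches
#'
#' `100 * n_success / n_targeted`; missing when there are no targeted
#' reaches.
#'
#' @inheritParams success_rate_by_trial
#' @return `summary` with an added `pct_success_by_reach` column.
#' @export
success_rate_by_reach <- function(summary) {
  dplyr::mutate(summary, pct_success_by_reach =
    pct_or_na(.data$n_success, .data$n_targeted))
}

#' Failure, first-reach-success and vain rates
#'
#' Complete-miss and contact-miss percentages use targeted reaches as the
#' denominator; the vain percentage uses total reaches; first-reach success
#' is the percentage of attempted trials whose first reach succeeded. All
#' are missing on zero denominators.
#'
#' @inheritParams success_rate_by_trial
#' @return `summary` with added columns `pct_complete_miss`,
#'   `pct_contact_miss`, `pct_other`, `pct_vain`,
#'   `pct_first_reach_success`.
#' @export
failure_and_vain_rates <- function(summary) {
  dplyr::mutate(
    summary,
    pct_complete_miss = pct_or_na(.data$n_complete_miss, .data$n_targeted),
    pct_contact_miss = pct_or_na(.data$n_contact_miss, .data$n_targeted),
    pct_other = pct_or_na(.data$n_other, .data$n_targeted),
    pct_vain = pct_or_na(.data$n_vain, .data$n_total_reaches),
    pct_first_reach_success =
      pct_or_na(.data$n_first_reach_success, .data$n_trials_attempted)
  )
}

#' All outcome percentage metrics
#'
#' Convenience wrapper adding every percentage column: success by trial,
#' success by targeted reach, complete/contact miss, other, vain and
#' first-reach success.
#'
#' @inheritParams success_rate_by_trial
#' @return `summary` with all `pct_*` columns added.
#' @export
outcome_rates <- function(summary) {
  failure_and_vain_rates(success_rate_by_reach(success_rate_by_trial(summary)))
}

#' Per-group outcome distribution on one day
#'
#' Fractions of targeted reaches falling into the success, complete-miss,
#' contact-miss and other categories, pooled across the subjects of each
#' group on the given day (per-subject weighting available as an option).
#' Fractions sum to 1 within each group.
#'
#' @param summaries Output of [summarize_sessions()], joined with a grouping
#'   column (e.g. genotype).
#' @param day Day to tabulate (e.g. the final training day).
#' @param by Name of the grouping column.
#' @param weighting `"pooled"` pools reaches across subjects; `"subject"`
#'   averages per-subject fractions instead.
#' @return Tibble with columns `by`-group, `label`, `fraction`.
#' @export
outcome_distribution <- function(summaries, day, by = "genotype",
                                 weighting = c("pooled", "subject")) {
  weighting <- match.arg(weighting)
  if (!by %in% names(summaries)) {
    abort(sprintf("grouping column '%s' not found; join it onto the summaries", by))
  }
  dat <- summaries[summaries$day == day, , drop = FALSE]
  labs <- c("success", "complete_miss", "contact_miss", "other")
  cols <- paste0("n_", labs)
  long <- tidyr::pivot_longer(
    dat[, c(by, "subject", cols, "n_targeted")],
    dplyr::all_of(cols), names_to = "label", values_to = "count"
  )
  long$label <- sub("^n_", "", long$label)
  if (weighting == "pooled") {
    totals <- dplyr::summarise(
      dplyr::group_by(dat, .data[[by]]),
      total_targeted = sum(.data$n_targeted), .groups = "drop"
    )
    out <- dplyr::summarise(
      dplyr::group_by(long, .data[[by]], .data$label),
      count = sum(.data$count), .groups = "drop"
    )
    out <- dplyr::left_join(out, totals, by = by)
    out$fraction <- out$count / out$total_targeted
    out <- out[, c(by, "label", "fraction")]
  } else {
    out <- dplyr::summarise(
      dplyr::group_by(long, .data[[by]], .data$label),
      fraction = mean(.data$count / .data$n_targeted, na.rm = TRUE),
      .groups = "drop"
    )
  }
  out$label <- factor(out$label, levels = labs)
  dplyr::arrange(out, .data[[by]], .data$label)
}

#' Geometric reach classifier
#'
#' Surrogate for manual outcome scoring when no annotations exist: a reach
#' made while the pellet is absent is `vain`; a targeted reach whose minimum
#' paw-pellet distance exceeds `contact_radius_px` is a `complete_miss`;
#' contact followed by pellet disappearance within `retrieval_lag` frames of
#' the retraction onset is a `success`; contact without retrieval is a
#' `contact_miss`. The residual manual category `other` is never emitted.
#'
#' @param reach One reach's points (`frame`, `x`, `y`).
#' @param pellet_track Tibble with `frame`, `x`, `y`, `likelihood` for the
#'   pellet over the session (e.g. [filter_track()] input columns of the
#'   pellet point, unfiltered).
#' @param contact_radius_px Contact distance threshold in pixels.
#' @param p_cutoff Likelihood above which the pellet counts as present.
#' @param retrieval_lag Frames after the reach end (the retraction onset)
#'   within which pellet disappearance counts as retrieval; the default
#'   covers a retraction at 240 fps.
#' @return A single label.
#' @export
auto_classify_reach <- function(reach, pellet_track, contact_radius_px = 15,
                                p_cutoff = 0.85, retrieval_lag = 25L) {
  if (is.null(pellet_track) || nrow(pellet_track) == 0) {
    abort("pellet track missing: geometric classifier unavailable")
  }
  f0 <- reach$frame[1]
  f1 <- reach$frame[nrow(reach)]
  at_start <- pellet_track[pellet_track$frame == f0, ]
  present <- nrow(at_start) > 0 && any(at_start$likelihood >= p_cutoff)
  if (!present) return("vain")
  span <- pellet_track$frame >= f0 & pellet_track$frame <= f1 &
    pellet_track$likelihood >= p_cutoff
  pellet_xy <- c(median(pellet_track$x[span]), median(pellet_track$y[span]))
  dmin <- min(sqrt((reach$x - pellet_xy[1])^2 + (reach$y - pellet_xy[2])^2))
  if (dmin > contact_radius_px) return("complete_miss")
  after <- pellet_track$frame > f1 & pellet_track$frame <= f1 + retrieval_lag
  # a sustained likelihood collapse (not a one-frame occlusion) marks removal
  removed <- sum(after) > 0 &&
    mean(pellet_track$likelihood[after] < p_cutoff) >= 0.3
  if (removed) "success" else "contact_miss"
}
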