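#' Default simulated groups
#'
#' Two genotype groups in the Door condition with learning effects on the
#' scale reported for this task: per-attempt success probability rising from
#' a low baseline toward a 45% (WT) versus 25% (KO) asymptote, and
#' trajectory noise, overshoot and vertical spread that shrink over days
#' (faster in WT).
#'
#' @param n_subjects Subjects per group (default 10, mirroring the balanced
#'   mixed-sex cohorts of the study design).
#' @return Tibble of per-group generative parameters, one row per group.
#' @export
default_sim_groups <- function(n_subjects = 10L) {
  tibble::tibble(
    group = c("WT", "KO"),
    genotype = c("WT", "KO"),
    condition = "door",
    n_subjects = as.integer(n_subjects),
    success_baseline = c(0.08, 0.06),
    success_asymptote = c(0.45, 0.25),
    success_rate = c(0.45, 0.35),
    noise_sigma_d1 = c(3, 3),
    noise_sigma_d8 = c(1.5, 2),
    overshoot_d1 = c(25, 25),
    overshoot_d8 = c(8, 14),
    vspread_d1 = c(14, 14),
    vspread_d8 = c(5, 9)
  )
}

#' Simulation configuration
#'
#' All generative parameters for a synthetic skilled-reaching cohort. The
#' defaults emulate the study's trial structure: 8 training days of 50
#' trials each, 13 s pellet-access windows recorded at 240 fps from the
#' side, with the pellet in a fixed divot beyond the slit.
#'
#' `success_*` columns of `groups` define the per-attempt (per targeted
#' reach) success probability
#' `p(day) = baseline + (asymptote - baseline) * (1 - exp(-rate * (day - 1)))`,
#' so the asymptote is on the success-by-reach scale. The `*_d1`/`*_d8`
#' column pairs define linear day trends for trajectory noise (px),
#' overshoot beyond the pellet on missed reaches (px), and vertical reach
#' spread (px).
#'
#' @param groups Per-group parameter tibble; see [default_sim_groups()].
#' @param days Training days (>= 2; default 8).
#' @param trials_per_day Trials per day (default 50).
#' @param fps Frames per second (default 240).
#' @param access_window Pellet access window per trial, seconds (default 13).
#' @param slit_x Pixel x of the slit plane; the tracking region lies beyond it.
#' @param pellet_xy Static pixel coordinate of the pellet divot.
#' @param bounds [tracking_bounds()] of the region outside the box.
#' @param no_try_rate Per-trial probability of zero reach attempts.
#' @param vain_rate Probability that a trial with a retrieval is followed by
#'   post-removal (vain) reaches.
#' @param dropout_prob Per-frame, per-point probability that a point is
#'   emitted with a near-zero likelihood (occlusion), rather than deleted.
#' @param attempts_lambda Poisson rate of extra attempts; the number of
#'   attempts a mouse would make in a trial without a retrieval is
#'   `1 + Poisson(attempts_lambda)`, capped at `max_attempts`.
#' @param max_attempts Cap on attempts per trial.
#' @param failure_mix Named probabilities over failed targeted reach labels
#'   (`complete_miss`, `contact_miss`, `other`); must sum to 1.
#' @param miss_offset_px Lateral aiming offset of complete-miss reaches.
#' @param reach_points_out,reach_points_back Samples on the outward and
#'   return limbs of a simulated reach.
#' @param contact_radius_px Paw-pellet distance under which a reach counts
#'   as contact for the geometric classifier.
#' @param paw Reaching paw label.
#' @param seed Integer seed; identical configurations (including seed)
#'   reproduce identical cohorts byte for byte.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(groups = default_sim_groups(),
                       days = 8L, trials_per_day = 50L, fps = 240,
                       access_window = 13,
                       slit_x = 250, pellet_xy = c(310, 200),
                       bounds = tracking_bounds(250, 640, 0, 480),
                       no_try_rate = 0.05, vain_rate = 0.25,
                       dropout_prob = 0.02,
                       attempts_lambda = 1.2, max_attempts = 6L,
                       failure_mix = c(complete_miss = 0.55,
                                       contact_miss = 0.40, other = 0.05),
                       miss_offset_px = 30,
                       reach_points_out = 12L, reach_points_back = 12L,
                       contact_radius_px = 15,
                       paw = "left_paw",
                       seed = 1L) {
  cfg <- structure(
    list(
      groups = tibble::as_tibble(groups), days = as.integer(days),
      trials_per_day = as.integer(trials_per_day), fps = fps,
      access_window = access_window, slit_x = slit_x,
      pellet_xy = as.numeric(pellet_xy), bounds = bounds,
      no_try_rate = no_try_rate, vain_rate = vain_rate,
      dropout_prob = dropout_prob, attempts_lambda = attempts_lambda,
      max_attempts = as.integer(max_attempts), failure_mix = failure_mix,
      miss_offset_px = miss_offset_px,
      reach_points_out = as.integer(reach_points_out),
      reach_points_back = as.integer(reach_points_back),
      contact_radius_px = contact_radius_px, paw = paw,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$no_try_rate, cfg$vain_rate, cfg$dropout_prob,
             cfg$groups$success_baseline, cfg$groups$success_asymptote,
             cfg$failure_mix)
  if (any(probs < 0 | probs > 1)) abort("all probabilities must lie in [0, 1]")
  if (abs(sum(cfg$failure_mix) - 1) > 1e-8) abort("failure_mix must sum to 1")
  if (!all(c("complete_miss", "contact_miss", "other") %in% names(cfg$failure_mix))) {
    abort("failure_mix needs complete_miss, contact_miss and other entries")
  }
  if (cfg$fps <= 0) abort("fps must be positive")
  if (cfg$days < 2) abort("need days >= 2")
  need <- c("group", "n_subjects", "success_baseline", "success_asymptote",
            "success_rate", "noise_sigma_d1", "noise_sigma_d8",
            "overshoot_d1", "overshoot_d8", "vspread_d1", "vspread_d8")
  miss <- setdiff(need, names(cfg$groups))
  if (length(miss) > 0) {
    abort(sprintf("groups is missing columns: %s", paste(miss, collapse = ", ")))
  }
  for (d in seq_len(cfg$days)) {
    for (g in seq_len(nrow(cfg$groups))) {
      vals <- c(
        sim_curve(cfg, cfg$groups$group[g], "noise_sigma", d),
        sim_curve(cfg, cfg$groups$group[g], "overshoot", d),
        sim_curve(cfg, cfg$groups$group[g], "vspread", d),
        sim_curve(cfg, cfg$groups$group[g], "success", d)
      )
      if (any(!is.finite(vals)) || any(vals < 0)) {
        abort(sprintf("curve values must be finite and nonnegative (day %d)", d))
      }
    }
  }
  invisible(cfg)
}

#' Evaluate a generative day curve
#'
#' `success` evaluates the saturating per-attempt success probability;
#' `noise_sigma`, `overshoot` and `vspread` interpolate linearly between
#' their day-1 and day-8-style endpoint values across `config$days`.
#'
#' @param config A [sim_config()].
#' @param group Group label.
#' @param which One of `"success"`, `"noise_sigma"`, `"overshoot"`,
#'   `"vspread"`.
#' @param day Day in `1:config$days` (vectorised).
#' @return Numeric curve value(s).
#' @export
sim_curve <- function(config, group, which, day) {
  g <- config$groups[config$groups$group == group, ]
  if (nrow(g) != 1) abort(sprintf("unknown group '%s'", group))
  if (any(day < 1 | day > config$days)) {
    abort(sprintf("day must lie in [1, %d]", config$days))
  }
  frac <- (day - 1) / (config$days - 1)
  switch(which,
    success = g$success_baseline +
      (g$success_asymptote - g$success_baseline) *
        (1 - exp(-g$success_rate * (day - 1))),
    noise_sigma = g$noise_sigma_d1 + (g$noise_sigma_d8 - g$noise_sigma_d1) * frac,
    overshoot = g$overshoot_d1 + (g$overshoot_d8 - g$overshoot_d1) * frac,
    vspread = g$vspread_d1 + (g$vspread_d8 - g$vspread_d1) * frac,
    abort(sprintf("unknown curve '%s'", which))
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d groups, %d days x %d trials, %g fps, %g s access, seed %d\n",
    nrow(x$groups), x$days, x$trials_per_day, x$fps, x$access_window, x$seed
  ))
  invisible(x)
}

# frames per trial
trial_frames <- function(config) as.integer(round(config$access_window * config$fps))

# deterministic per-(subject, day) sub-seed, kept below 2^31
pose_subseed <- function(config, subject, day) {
  h <- sum(utf8ToInt(subject) * seq_along(utf8ToInt(subject)))
  as.integer((as.numeric(config$seed) * 7919 + h * 131 + day * 17) %% 2147483629)
}
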