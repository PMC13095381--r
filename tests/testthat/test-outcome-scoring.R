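make_session <- function(labels_by_trial, subject = "m1", day = 1L) {
  # labels_by_trial: list of character vectors (possibly empty = no try)
  reaches <- purrr::imap_dfr(labels_by_trial, function(labs, t) {
    if (length(labs) == 0) return(tibble::tibble())
    tibble::tibble(
      subject = subject, day = day, trial = as.integer(t),
      ordinal = seq_along(labs), label = labs
    )
  })
  trials <- tibble::tibble(
    subject = subject, day = day,
    trial = seq_along(labels_by_trial),
    no_try = lengths(labels_by_trial) == 0
  )
  list(reaches = reaches, trials = trials)
}

test_that("session summaries count trials and the label partition correctly", {
  # 50 trials: 10 no-try, 20 with a success, 20 attempted failures
  labs <- c(
    replicate(10, character(0), simplify = FALSE),
    replicate(20, c("complete_miss", "success"), simplify = FALSE),
    replicate(20, "complete_miss", simplify = FALSE)
  )
  s <- make_session(labs)
  got <- summarize_session(s$reaches, s$trials)
  expect_equal(got$n_trials, 50)
  expect_equal(got$n_no_try, 10)
  expect_equal(got$n_trials_attempted, 40)
  expect_equal(got$n_success_trials, 20)

  s2 <- make_session(list(
    c("success", "complete_miss", "vain"),
    c("success", "contact_miss", "vain", "vain"),
    c("success", "complete_miss"),
    c("success", "complete_miss", "contact_miss", "vain"),
    c("success", "other")
  ))
  got2 <- summarize_session(s2$reaches, s2$trials)
  expect_equal(got2$n_success, 5)
  expect_equal(got2$n_complete_miss, 3)
  expect_equal(got2$n_contact_miss, 2)
  expect_equal(got2$n_vain, 4)
  expect_equal(got2$n_other, 1)
  expect_equal(got2$n_targeted, 11)
  expect_equal(got2$n_total_reaches, 15)

  # percentage arithmetic on the same partition
  r <- outcome_rates(got2)
  expect_equal(r$pct_success_by_reach, 100 * 5 / 11, tolerance = 1e-12)
  expect_equal(r$pct_complete_miss, 100 * 3 / 11, tolerance = 1e-12)
  expect_equal(r$pct_contact_miss, 100 * 2 / 11, tolerance = 1e-12)
  expect_equal(r$pct_vain, 100 * 4 / 15, tolerance = 1e-12)

  mixed <- make_session(list("success"), subject = "m2", day = 2L)
  expect_error(
    summarize_session(
      dplyr::bind_rows(s$reaches, mixed$reaches),
      dplyr::bind_rows(s$trials, mixed$trials)
    ),
    "single subject-day"
  )
  expect_error(
    summarize_sessions(
      dplyr::mutate(s2$reaches, label = replace(label, 1, "slip")), s2$trials
    ),
    "unknown reach label"
  )
})

test_that("rates are missing (never errors) on zero denominators", {
  all_nt <- make_session(replicate(5, character(0), simplify = FALSE))
  got <- outcome_rates(summarize_session(all_nt$reaches, all_nt$trials))
  expect_true(is.na(got$pct_success_by_trial))
  expect_true(is.na(got$pct_success_by_reach))
  expect_true(is.na(got$pct_complete_miss))
  expect_true(is.na(got$pct_first_reach_success))
  # vain-only session: targeted denominator zero, vain uses total reaches
  vo <- make_session(list(c("vain", "vain")))
  got2 <- outcome_rates(summarize_session(vo$reaches, vo$trials))
  expect_true(is.na(got2$pct_success_by_reach))
  expect_equal(got2$pct_vain, 100)
})

test_that("success by reach can undercut success by trial with repeated attempts", {
  s <- make_session(replicate(10, c("complete_miss", "success"), simplify = FALSE))
  got <- outcome_rates(summarize_session(s$reaches, s$trials))
  expect_equal(got$pct_success_by_trial, 100)
  expect_equal(got$pct_success_by_reach, 50)
  expect_lte(got$pct_success_by_reach, got$pct_success_by_trial)
})

test_that("first-reach success depends only on the ordinal-1 reach", {
  s <- make_session(list(
    c("success"),                       # first-reach success
    c("complete_miss", "success"),      # success but not on first reach
    c("contact_miss")                   # failure
  ))
  got <- outcome_rates(summarize_session(s$reaches, s$trials))
  expect_equal(got$n_first_reach_success, 1)
  expect_equal(got$pct_first_reach_success, 100 / 3, tolerance = 1e-12)
})

test_that("summary counts equal simulator ground truth and satisfy identities", {
  cfg <- sim_config(groups = default_sim_groups(4), days = 3,
                    trials_per_day = 25, seed = 40)
  co <- simulate_cohort(cfg)
  summ <- outcome_rates(summarize_sessions(co$reaches, co$trials))
  # exhaustive comparison against the ground-truth table
  gt_counts <- dplyr::summarise(
    dplyr::group_by(co$reaches, subject, day),
    n_success = sum(label == "success"), n_vain = sum(label == "vain"),
    n_total = dplyr::n(), .groups = "drop"
  )
  cmp <- dplyr::left_join(summ, gt_counts, by = c("subject", "day"))
  expect_equal(cmp$n_success.x, cmp$n_success.y)
  expect_equal(cmp$n_vain.x, cmp$n_vain.y)
  expect_equal(cmp$n_total_reaches, cmp$n_total)
  # partition identities
  expect_equal(
    summ$n_success + summ$n_complete_miss + summ$n_contact_miss + summ$n_other,
    summ$n_targeted
  )
  expect_equal(summ$n_targeted + summ$n_vain, summ$n_total_reaches)
  pct <- summ[, grep("^pct_", names(summ))]
  expect_true(all(as.matrix(pct) >= 0 & as.matrix(pct) <= 100, na.rm = TRUE))
  # targeted percentages sum to exactly 100 where defined
  ok <- summ$n_targeted > 0
  expect_equal(
    summ$pct_success_by_reach[ok] + summ$pct_complete_miss[ok] +
      summ$pct_contact_miss[ok] + summ$pct_other[ok],
    rep(100, sum(ok)),
    tolerance = 1e-9
  )
})

test_that("outcome distributions normalise and pool as count-weighted means", {
  s <- make_session(replicate(4, "success", simplify = FALSE))
  summ <- summarize_session(s$reaches, s$trials)
  summ$genotype <- "WT"
  dist <- outcome_distribution(summ, day = 1)
  expect_equal(dist$fraction[dist$label == "success"], 1)
  expect_equal(sum(dist$fraction), 1, tolerance = 1e-12)

  set.seed(41)
  cfg <- sim_config(groups = default_sim_groups(4), days = 2,
                    trials_per_day = 20, seed = 41)
  co <- simulate_cohort(cfg)
  summ2 <- summarize_sessions(co$reaches, co$trials)
  summ2 <- dplyr::left_join(summ2, co$manifest, by = "subject")
  pooled <- outcome_distribution(summ2, day = 2)
  by_geno <- split(pooled, pooled$genotype)
  for (d in by_geno) expect_equal(sum(d$fraction), 1, tolerance = 1e-12)
  # pooled fractions equal the count-weighted mean of per-subject fractions
  day2 <- summ2[summ2$day == 2 & summ2$genotype == "WT", ]
  w <- day2$n_targeted / sum(day2$n_targeted)
  manual <- sum(w * (day2$n_success / day2$n_targeted))
  expect_equal(
    pooled$fraction[pooled$genotype == "WT" & pooled$label == "success"],
    manual, tolerance = 1e-12
  )
})

test_that("geometric classifier applies availability, contact and retrieval rules", {
  pellet_track <- tibble::tibble(
    frame = 0:99, x = 310, y = 200,
    likelihood = c(rep(0.97, 60), rep(0.01, 40))
  )
  near <- tibble::tibble(frame = 10:20, x = seq(260, 310, length.out = 11), y = 200)
  far <- tibble::tibble(frame = 10:20, x = seq(260, 290, length.out = 11), y = 240)
  late <- tibble::tibble(frame = 70:80, x = seq(260, 310, length.out = 11), y = 200)

  # reach entirely after pellet removal
  expect_equal(auto_classify_reach(late, pellet_track), "vain")
  # min distance 40 px with radius 15 px
  expect_equal(auto_classify_reach(far, pellet_track, contact_radius_px = 15),
               "complete_miss")
  # contact without removal within the lag
  expect_equal(auto_classify_reach(near, pellet_track), "contact_miss")
  # contact followed by sustained pellet disappearance
  retrieved <- tibble::tibble(
    frame = 0:99, x = 310, y = 200,
    likelihood = c(rep(0.97, 21), rep(0.01, 79))
  )
  expect_equal(auto_classify_reach(near, retrieved), "success")
  expect_error(auto_classify_reach(near, NULL), "pellet track missing")
})

test_that("geometric labels recover simulator ground truth on noiseless trials", {
  cfg <- sim_config(groups = noiseless_groups(3), days = 3, trials_per_day = 10,
                    access_window = 3, dropout_prob = 0, seed = 42)
  co <- simulate_cohort(cfg)
  pl <- run_reach_pipeline(co, labels = "auto")
  gt <- co$reaches[, c("subject", "day", "trial", "ordinal", "label")]
  names(gt)[5] <- "gt_label"
  m <- dplyr::inner_join(
    pl$detections[, c("subject", "day", "trial", "ordinal", "label")],
    gt, by = c("subject", "day", "trial", "ordinal")
  )
  expect_gt(nrow(m), 100)
  expect_gte(mean(m$label == m$gt_label), 0.95)
  # every mismatch is the residual manual category the classifier never emits
  expect_true(all(m$gt_label[m$label != m$gt_label] == "other"))
})
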