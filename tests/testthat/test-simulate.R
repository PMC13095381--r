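test_that("configuration invariants are enforced", {
  expect_error(sim_config(no_try_rate = 1.5), "probabilities")
  expect_error(sim_config(days = 1), "days")
  expect_error(sim_config(fps = 0), "fps")
  g <- default_sim_groups()
  g$vspread_d8 <- c(-1, -1)
  expect_error(sim_config(groups = g), "nonnegative")
  expect_error(
    sim_config(failure_mix = c(complete_miss = 0.5, contact_miss = 0.5, other = 0.5)),
    "sum to 1"
  )
})

test_that("a noiseless success trajectory touches the pellet at the apex", {
  g <- noiseless_groups()
  cfg <- sim_config(groups = g, dropout_prob = 0)
  set.seed(30)
  traj <- simulate_reach_trajectory(cfg, 1, "WT", "success")
  d <- sqrt((traj$x - cfg$pellet_xy[1])^2 + (traj$y - cfg$pellet_xy[2])^2)
  expect_equal(min(d), 0, tolerance = 1e-12)
  expect_equal(which.min(d), cfg$reach_points_out)
  # unimodal distance profile: strictly decreasing out, increasing back
  expect_true(all(diff(d[1:cfg$reach_points_out]) < 0))
  expect_true(all(diff(d[cfg$reach_points_out:length(d)]) > 0))
  # miss apex overshoots the pellet in x by the day's overshoot
  missd <- simulate_reach_trajectory(cfg, 1, "WT", "complete_miss")
  expect_equal(max(missd$x), cfg$pellet_xy[1] + sim_curve(cfg, "WT", "overshoot", 1),
               tolerance = 1e-9)
  expect_error(simulate_reach_trajectory(cfg, 1, "WT", "slip"), "unknown outcome")
})

test_that("same seed and arguments reproduce an identical trajectory", {
  cfg <- sim_config()
  set.seed(31)
  a <- simulate_reach_trajectory(cfg, 3, "KO", "contact_miss")
  set.seed(31)
  b <- simulate_reach_trajectory(cfg, 3, "KO", "contact_miss")
  expect_identical(a, b)
})

test_that("degenerate trial probabilities behave as stated", {
  cfg1 <- sim_config(no_try_rate = 1, seed = 5)
  set.seed(5)
  for (i in 1:20) {
    tr <- simulate_trial(cfg1, 1, "WT")
    expect_true(tr$no_try)
    expect_equal(nrow(tr$reaches), 0)
  }
  g <- default_sim_groups()
  g$success_baseline <- 1
  g$success_asymptote <- 1
  cfg2 <- sim_config(groups = g, no_try_rate = 0, vain_rate = 0,
                     attempts_lambda = 0, seed = 6)
  set.seed(6)
  for (i in 1:20) {
    tr <- simulate_trial(cfg2, 1, "WT")
    expect_equal(tr$reaches$label, "success")
  }
})

test_that("trial-level success frequency matches the imposed binomial rate", {
  g <- default_sim_groups(1)[1, ]
  g$success_baseline <- 0.4
  g$success_asymptote <- 0.4
  cfg <- sim_config(groups = g, no_try_rate = 0, vain_rate = 0,
                    attempts_lambda = 0, days = 2, trials_per_day = 5000,
                    seed = 32)
  co <- simulate_cohort(cfg)
  # single attempt per trial: trial success probability equals attempt-level p
  per_trial <- dplyr::count(co$reaches, subject, day, trial)
  expect_true(all(per_trial$n == 1))
  p_hat <- mean(co$reaches$label == "success")
  se <- sqrt(0.4 * 0.6 / nrow(co$reaches))
  expect_lt(abs(p_hat - 0.4), 3 * se)
})

test_that("ground-truth labels partition attempts with at most one success per trial", {
  cfg <- sim_config(groups = default_sim_groups(3), days = 4,
                    trials_per_day = 20, access_window = 3, seed = 33)
  co <- simulate_cohort(cfg)
  expect_true(all(co$reaches$label %in% reach_labels()))
  per_trial <- dplyr::summarise(
    dplyr::group_by(co$reaches, subject, day, trial),
    n_succ = sum(label == "success"), .groups = "drop"
  )
  expect_true(all(per_trial$n_succ <= 1))
  # no_try trials have zero reaches
  nt <- co$trials[co$trials$no_try, ]
  joined <- dplyr::semi_join(co$reaches, nt, by = c("subject", "day", "trial"))
  expect_equal(nrow(joined), 0)
  # vain reaches lie outside the pellet-present interval
  v <- dplyr::inner_join(
    co$reaches[co$reaches$label == "vain", ],
    co$trials[, c("subject", "day", "trial", "pellet_end")],
    by = c("subject", "day", "trial")
  )
  expect_true(all(v$start_frame > v$pellet_end))
  # reach intervals ordered and disjoint within trials
  ord <- dplyr::group_by(co$reaches, subject, day, trial)
  ord <- dplyr::summarise(
    ord,
    ok = all(diff(start_frame) > 0) && all(start_frame[-1] > end_frame[-dplyr::n()]),
    .groups = "drop"
  )
  expect_true(all(ord$ok))
})

test_that("simulated cohorts are reproducible byte for byte on disk", {
  cfg <- sim_config(groups = default_sim_groups(1), days = 2,
                    trials_per_day = 3, access_window = 1, seed = 34)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_cohort(cfg, dir = d1)
  simulate_cohort(cfg, dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(
      unname(tools::md5sum(file.path(d1, f))),
      unname(tools::md5sum(file.path(d2, f))),
      info = f
    )
  }
})

test_that("writing a 2-subject 2-day cohort yields 4 pose tables and a 2-row manifest", {
  cfg <- sim_config(groups = default_sim_groups(2)[1, ], days = 2,
                    trials_per_day = 3, access_window = 1, seed = 35)
  d <- withr::local_tempdir()
  co <- simulate_cohort(cfg, dir = d)
  expect_length(list.files(file.path(d, "poses")), 4)
  man <- readr::read_tsv(file.path(d, "manifest.tsv"), show_col_types = FALSE)
  expect_equal(nrow(man), 2)
  # ground-truth reach count is recoverable from the emitted table
  gt <- readr::read_tsv(file.path(d, "ground_truth.tsv"), show_col_types = FALSE)
  expect_equal(sum(!gt$no_try), nrow(co$reaches))
  expect_error(write_cohort(co, file.path("/proc", "nope")), "cannot write")
})

test_that("ground-truth reach intervals survive filtering when dropout is off", {
  cfg <- sim_config(groups = default_sim_groups(2), days = 2,
                    trials_per_day = 10, access_window = 3,
                    dropout_prob = 0, seed = 36)
  co <- simulate_cohort(cfg)
  for (s in c("WT01", "KO02")) {
    track <- simulate_session_poses(co, s, 2)
    ft <- filter_track(track, cfg$paw, 0.85, cfg$bounds)
    gt <- co$reaches[co$reaches$subject == s & co$reaches$day == 2, ]
    for (i in seq_len(nrow(gt))) {
      n_in <- sum(ft$frame >= gt$start_frame[i] & ft$frame <= gt$end_frame[i])
      expect_gte(n_in, 6)
    }
  }
})

test_that("declared decreasing day curves decrease in Monte-Carlo expectation", {
  cfg <- sim_config(seed = 37)
  for (w in c("noise_sigma", "overshoot", "vspread")) {
    v <- sim_curve(cfg, "WT", w, 1:8)
    expect_true(all(diff(v) <= 0))
  }
  # expected delta-X (driven by overshoot) shrinks from day 1 to day 8
  set.seed(37)
  dx <- function(day) {
    mean(vapply(1:1000, function(i) {
      reach_delta_x(
        simulate_reach_trajectory(cfg, day, "WT", "complete_miss"),
        slit_x = cfg$slit_x
      )
    }, numeric(1)))
  }
  expect_lt(dx(8), dx(1))
})
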