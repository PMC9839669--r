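sched <- build_default_schedule()
cfg <- default_sim_config()

test_that("zero-variability constant-HR profile gives identical 1-s intervals", {
  p <- autonomic_profile(rep(60, 6), 0, 0)
  rr <- generate_rr_trajectory(p, sched, 1)
  expect_true(all(abs(rr$intervals_s - 1) < 1e-12))
  expect_equal(rmssd(rr), 0)
  expect_equal(sdnn(rr), 0)
  # beats cover the recording
  expect_gt(max(rr$beat_times_s), sched$total_dur_s - 2)
})

test_that("trajectories are deterministic under a fixed seed", {
  p <- draw_autonomic_profile("FM", 2, cfg, 3)
  expect_identical(generate_rr_trajectory(p, sched, 42)$beat_times_s,
                   generate_rr_trajectory(p, sched, 42)$beat_times_s)
  expect_false(identical(generate_rr_trajectory(p, sched, 42)$beat_times_s,
                         generate_rr_trajectory(p, sched, 43)$beat_times_s))
})

test_that("degenerate profiles are rejected", {
  expect_error(autonomic_profile(rep(0, 6), 0.02, 0.03))
  expect_error(autonomic_profile(rep(60, 6), -1, 0.03))
})

test_that("FM stress reactivity matches the calibrated group rise", {
  # group-mean HR rise baseline -> stress1 should be ~10.6 bpm for FM
  n <- 153  # 3 cluster blocks of 51
  seeds <- derive_seeds(7, n)
  rise <- sapply(seq_len(n), function(i) {
    cl <- c(rep(1, 9), rep(2, 21), rep(3, 21))[(i - 1) %% 51 + 1]
    pr <- draw_autonomic_profile("FM", cl, cfg, seeds[i, "subject"])
    pr$hr_bpm[["stress1"]] - pr$hr_bpm[["baseline"]]
  })
  expect_lt(abs(mean(rise) - 10.6), 1.5)
})

test_that("realized window metrics track the profile within 15%", {
  seeds <- derive_seeds(11, 40)
  rat <- sapply(1:40, function(i) {
    pr <- draw_autonomic_profile("control", NA, cfg, seeds[i, "subject"])
    rr <- generate_rr_trajectory(pr, sched, seeds[i, "rr"])
    ps <- phase_summaries(rr, sched, "x")
    b <- ps[ps$window == "baseline", ]
    c(b$rmssd_s / pr$rmssd_s, b$sdnn_s / pr$sdnn_s)
  })
  expect_lt(abs(mean(rat[1, ]) - 1), 0.15)
  expect_lt(abs(mean(rat[2, ]) - 1), 0.15)
})

test_that("instantaneous mean HR dominates 60/RRmean (Jensen)", {
  seeds <- derive_seeds(13, 20)
  for (i in 1:20) {
    pr <- draw_autonomic_profile("FM", 1 + (i %% 3), cfg, seeds[i, "subject"])
    rr <- generate_rr_trajectory(pr, sched, seeds[i, "rr"])
    ps <- phase_summaries(rr, sched, "x")
    expect_true(all(ps$hr_bpm >= 60 / ps$rr_mean_s - 1e-9))
  }
})

test_that("subjects respect instrument ranges and group structure", {
  seeds <- derive_seeds(17, 60)
  for (i in 1:60) {
    grp <- if (i %% 2) "FM" else "control"
    cl <- if (grp == "FM") 1 + (i %% 3) else NA
    s <- generate_subject(sprintf("S%d", i), grp, cl, cfg, seeds[i, "subject"])
    expect_true(s$pss >= 0 && s$pss <= 40)
    expect_true(s$pcs >= 0 && s$pcs <= 52)
    expect_true(s$stai_a >= 20 && s$stai_a <= 80)
    expect_true(s$stai_b >= 20 && s$stai_b <= 80)
    expect_true(s$fiq_total >= 0 && s$fiq_total <= 100)
    items <- unlist(s[paste0("fiq_item", 1:10)])
    expect_true(all(is.na(items) | (items >= 0 & items <= 10)))
    expect_identical(s$physically_active, s$lpa_score >= 7)
    if (grp == "control") expect_true(is.na(s$true_cluster))
  }
})

test_that("FM covariates are calibrated to the group distributions", {
  seeds <- derive_seeds(23, 2000)
  bmi <- sapply(1:2000, function(i)
    generate_subject("x", "FM", 1 + (i %% 3), cfg, seeds[i, "subject"])$bmi)
  expect_lt(abs(mean(bmi) - 28.2), 0.3)
})

test_that("NRS ratings: clipping, zero-noise determinism, stress effect", {
  cfg0 <- default_sim_config()
  cfg0$nrs$noise_sd <- 0
  cfg0$nrs$stress_effect <- 0
  cfg0$nrs$stress_base <- rep(3, 4)
  cfg0$nrs$pain_base <- rep(3, 4)
  r <- generate_nrs_ratings("FM", 1, cfg0, 1)
  # zero effect, zero rating noise: constant except the subject-level draw
  expect_equal(length(unique(r$nrs_stress)), 1)
  # clipping: extreme baseline stays in range
  cfg0$nrs$stress_base <- rep(12, 4)
  r2 <- generate_nrs_ratings("FM", 1, cfg0, 2)
  expect_true(all(r2$nrs_stress >= 0 & r2$nrs_stress <= 10))
  # default config: +2 stress effect recovered over many subjects
  d <- do.call(rbind, lapply(1:800, function(i)
    generate_nrs_ratings("FM", 1 + (i %% 3), cfg, i)))
  eff <- mean(d$nrs_stress[d$timepoint == 3]) -
    mean(d$nrs_stress[d$timepoint == 1])
  expect_lt(abs(eff - 2), 0.2)
})

test_that("cohort generation is deterministic and correctly sized", {
  small <- default_sim_config(n_fm = 4, n_control = 2, master_seed = 5)
  c1 <- generate_cohort(small)
  c2 <- generate_cohort(small)
  expect_identical(c1$truth_hrv, c2$truth_hrv)
  expect_identical(c1$subjects, c2$subjects)
  expect_equal(nrow(c1$subjects), 6)
  expect_equal(nrow(c1$truth_hrv), 6 * 6)   # 6 windows per subject
  # deterministic largest-remainder allocation: 9/21/21 of 51
  expect_equal(as.vector(table(allocate_clusters(51, c(9, 21, 21) / 51))),
               c(9, 21, 21))
})

test_that("waveform regeneration from the cohort is reproducible", {
  small <- default_sim_config(n_fm = 1, n_control = 1, master_seed = 5, fs = 500)
  coh <- generate_cohort(small)
  expect_identical(cohort_waveform(coh, 1)$samples,
                   cohort_waveform(coh, 1)$samples)
  w <- cohort_waveform(coh, 2)
  expect_equal(length(w$samples), 1200 * 500)
})
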