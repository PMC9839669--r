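test_that("long table has 5 rows per complete subject with relax1 reference", {
  cfg <- default_sim_config(n_fm = 5, n_control = 3, master_seed = 21)
  coh <- generate_cohort(cfg)
  rows <- build_long_table(coh$truth_hrv, coh$subjects, "hr_bpm")
  expect_equal(nrow(rows), 8 * 5)
  expect_equal(levels(rows$time)[1], "relax1")
  expect_equal(levels(rows$group), c("control", "FM"))
  # baseline constant within subject
  bvar <- tapply(rows$baseline, rows$subject_id, function(b) max(b) - min(b))
  expect_true(all(bvar == 0))
  # a subject without baseline is excluded with a warning
  broken <- coh$truth_hrv
  broken$hr_bpm[broken$subject_id == "S001" & broken$window == "baseline"] <- NA
  expect_warning(rows2 <- build_long_table(broken, coh$subjects, "hr_bpm"),
                 "S001")
  expect_equal(nrow(rows2), 7 * 5)
})

test_that("GLS with rho = 0 reproduces ordinary least squares exactly", {
  d <- simulate_long_null(1)
  f0 <- fit_gls(y ~ group * time + baseline, d, rho = 0)
  ols <- stats::lm(y ~ group * time + baseline, d)
  expect_lt(max(abs(f0$coefficients$estimate - unname(stats::coef(ols)))), 1e-10)
})

test_that("feasible GLS matches the reference implementation on balanced data", {
  skip_if_not_installed("nlme")
  d <- simulate_long_null(2)
  f <- fit_gls(y ~ group * time + baseline, d)
  g <- nlme::gls(y ~ group * time + baseline, data = d,
                 correlation = nlme::corCompSymm(form = ~ 1 | subject_id))
  expect_equal(f$coefficients$estimate, unname(stats::coef(g)), tolerance = 1e-6)
  rho_ref <- stats::coef(g$modelStruct$corStruct, unconstrained = FALSE)
  expect_lt(abs(f$rho - unname(rho_ref)), 0.05)
  expect_true(f$converged)
  # CI ordering invariant
  expect_true(all(f$coefficients$ci_low <= f$coefficients$estimate))
  expect_true(all(f$coefficients$estimate <= f$coefficients$ci_high))
})

test_that("exchangeable rho is recovered from balanced repeated measures", {
  rhos <- sapply(1:30, function(s) fit_gls(y ~ group * time + baseline,
                                           simulate_long_null(s, rho = 0.5))$rho)
  expect_lt(abs(mean(rhos) - 0.5), 0.1)
})

test_that("rank-deficient designs fail with the aliased column named", {
  d <- simulate_long_null(3)
  d$dup <- d$baseline
  expect_error(fit_gls(y ~ baseline + dup, d), "dup")
})

test_that("baseline comparisons reproduce the printed contingency p-values", {
  p_smoke <- chisq_yates_2x2(12, 39, 2, 29)$p.value
  expect_equal(round(p_smoke, 3), 0.091)
  p_act <- chisq_yates_2x2(20, 31, 16, 15)$p.value
  expect_equal(round(p_act, 3), 0.386)
})

test_that("baseline comparison table carries both test conventions", {
  cfg <- default_sim_config(n_fm = 12, n_control = 10, master_seed = 31)
  coh <- generate_cohort(cfg)
  suppressWarnings(tab <- baseline_comparisons(coh$subjects, coh$truth_hrv))
  expect_true(all(c("student_t", "mann_whitney") %in% tab$method))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  hrbase <- tab[tab$variable == "hr_bpm" & tab$window == "baseline", ]
  expect_equal(nrow(hrbase), 2)
  # identical groups: t = 0, p = 1
  x <- c(1, 2, 3, 4)
  tt <- stats::t.test(x, x, var.equal = TRUE)
  expect_equal(unname(tt$statistic), 0)
  expect_equal(tt$p.value, 1)
})

test_that("ANOVA + Tukey: identical groups, k = 2 equivalence, power", {
  g3 <- rep(c("a", "b", "c"), each = 10)
  v <- rep(c(1, 2, 3), each = 10) * 0 + rep(seq(0.1, 1, 0.1), 3)
  res <- anova_tukey(v, g3)
  expect_lt(res$anova$F, 1e-10)
  expect_true(all(res$tukey$p_adj > 0.999))
  # two groups: Tukey p equals pooled-variance t-test p
  set.seed(9)
  x <- rnorm(12); y <- rnorm(15) + 0.7
  res2 <- anova_tukey(c(x, y), rep(c("a", "b"), c(12, 15)))
  pt <- stats::t.test(x, y, var.equal = TRUE)$p.value
  expect_equal(res2$tukey$p_adj, pt, tolerance = 1e-9)
  # a clearly shifted third group is detected
  set.seed(10)
  hits <- sapply(1:50, function(i) {
    v <- c(rnorm(20), rnorm(20), rnorm(20) + 5)
    g <- rep(c("a", "b", "c"), each = 20)
    r <- anova_tukey(v, g)
    all(r$tukey$p_adj[grepl("c", r$tukey$pair)] < 0.001)
  })
  expect_gt(mean(hits), 0.95)
  # undersized groups are excluded with a warning, remaining groups tested
  expect_warning(r3 <- anova_tukey(c(rnorm(10), rnorm(10), 1),
                                   rep(c("a", "b", "c"), c(10, 10, 1))))
  expect_equal(nrow(r3$tukey), 1)
})

test_that("injected stress2 attenuation is recovered by the GLS", {
  delta <- -4.4
  est <- sapply(1:40, function(s) {
    d <- simulate_long_null(s + 500, delta_s2 = delta)
    f <- fit_gls(y ~ group * time + baseline, d)
    f$coefficients$estimate[f$coefficients$term == "groupFM:timestress2"]
  })
  expect_lt(abs(mean(est) - delta), 0.5)
})
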