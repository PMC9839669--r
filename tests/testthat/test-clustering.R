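test_that("z-transform standardises and is location-scale invariant", {
  expect_equal(z_transform(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(1)
  x <- rnorm(50)
  z <- z_transform(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(stats::sd(z), 1)
  expect_equal(z_transform(3 * x - 7), z, tolerance = 1e-12)
  expect_error(z_transform(rep(2, 10)), "variance")
  expect_error(z_transform(1))
})

test_that("feasible configurations follow the published set and the rule", {
  cfgs <- enumerate_feasible_configs(51, c("delta_hr", "delta_rr_mean"),
                                     mode = "published")
  expect_length(cfgs, 5)
  expect_equal(sum(sapply(cfgs, `[[`, "d") == 2), 1)
  expect_equal(sum(sapply(cfgs, `[[`, "d") == 1), 4)
  # rule mode applies the inequality literally: k = 5 allowed at d = 1, n = 51
  cfgs2 <- enumerate_feasible_configs(51, c("delta_rr_mean"), max_k = 5,
                                      mode = "rule")
  expect_true(any(sapply(cfgs2, function(c) c$d == 1 && c$k == 5)))
  expect_false(any(sapply(cfgs2, function(c) c$k == 6)))
  expect_error(enumerate_feasible_configs(19))
  # n = 20 in rule mode: only (d=1, k=2) per variable
  cfgs3 <- enumerate_feasible_configs(20, c("a", "b"), max_k = 5, mode = "rule")
  expect_true(all(sapply(cfgs3, function(c) c$d == 1 && c$k == 2)))
})

test_that("k-means solves the two-pair example and degenerate cases", {
  res <- kmeans_reactivity(c(0, 0.1, 10, 10.1), 2, seed = 1)
  expect_equal(sort(res$sizes), c(2, 2))
  expect_equal(res$wss, 0.01)
  expect_equal(res$assignments[1], res$assignments[2])
  expect_equal(res$assignments[3], res$assignments[4])
  # k = n gives zero WSS
  expect_equal(kmeans_reactivity(c(1, 5, 9), 3, seed = 2)$wss, 0)
  # determinism under seed
  set.seed(99)
  x <- rnorm(30)
  expect_identical(kmeans_reactivity(x, 3, seed = 7)$assignments,
                   kmeans_reactivity(x, 3, seed = 7)$assignments)
  expect_error(kmeans_reactivity(c(1, 1, 1), 2, seed = 1), "distinct")
})

test_that("k-means attains the exhaustive-enumeration optimum on small sets", {
  set.seed(42)
  ok <- 0; runs <- 120
  for (r in seq_len(runs)) {
    n <- sample(6:12, 1); k <- sample(2:3, 1)
    x <- rnorm(n)
    res <- kmeans_reactivity(x, k, seed = r, n_init = 100)
    if (abs(res$wss - brute_kmeans_1d(x, k)) < 1e-9) ok <- ok + 1
  }
  expect_gte(ok / runs, 0.99)
  # multidimensional check against full assignment enumeration
  for (r in 1:10) {
    X <- matrix(rnorm(14), 7, 2)
    res <- kmeans_reactivity(X, 2, seed = r)
    expect_equal(res$wss, brute_kmeans_nd(X, 2), tolerance = 1e-9)
  }
})

test_that("minimum-WSS selection and tie-breaking follow the rules", {
  r1 <- structure(list(wss = 5, config = list(vars = "a", d = 1, k = 2)),
                  class = "hrv_kmeans")
  r2 <- structure(list(wss = 3, config = list(vars = c("a", "b"), d = 2, k = 2)),
                  class = "hrv_kmeans")
  expect_identical(select_clustering(list(r1, r2)), r2)
  expect_identical(select_clustering(list(r1)), r1)
  # equal WSS: smaller d wins
  r3 <- structure(list(wss = 5, config = list(vars = c("a", "b"), d = 2, k = 2)),
                  class = "hrv_kmeans")
  expect_identical(select_clustering(list(r3, r1)), r1)
})

test_that("three well-separated RR-reactivity modes select (delta_rr_mean, k = 3)", {
  set.seed(5)
  truth <- rep(1:3, c(9, 21, 21))
  mu <- c(-0.165, -0.09, -0.06)
  sigma <- min(diff(mu)) / 3          # 3-SD separation between adjacent modes
  drr <- rnorm(51, mu[truth], sigma)
  # HR reactivity physiologically tied to RR reactivity but noisier, so its
  # modes blur
  dhr <- -60 * drr / 0.7^2 + rnorm(51, 0, 4)
  react <- data.frame(subject_id = sprintf("S%02d", 1:51),
                      delta_hr = dhr, delta_rr_mean = drr)
  cand <- run_feasible_clusterings(react, seed = 1)
  expect_length(cand, 5)
  sel <- select_clustering(cand)
  expect_equal(sel$config$vars, "delta_rr_mean")
  expect_equal(sel$config$k, 3)
})

test_that("well-separated modes are recovered and labels are stabilised", {
  skip_if_not_installed("mclust")
  hits <- sapply(1:100, function(r) {
    set.seed(r)
    truth <- rep(1:3, c(9, 21, 21))
    x <- rnorm(51, c(-6, 0, 6)[truth], 1)   # 6-SD separation
    res <- kmeans_reactivity(z_transform(x), 3, seed = r)
    mclust::adjustedRandIndex(res$assignments, truth) >= 0.9
  })
  expect_gte(mean(hits), 0.95)
  # relabelling by baseline HR makes cluster 1 the lowest-HR cluster
  set.seed(3)
  truth <- rep(1:3, c(9, 21, 21))
  x <- rnorm(51, c(-6, 0, 6)[truth], 1)
  res <- kmeans_reactivity(z_transform(x), 3, seed = 11)
  res$subject_id <- sprintf("S%02d", 1:51)
  hr <- 60 + 8 * truth + rnorm(51, 0, 0.5)   # baseline HR rises with true cluster
  summ <- data.frame(subject_id = res$subject_id, window = "baseline",
                     hr_bpm = hr, rr_mean_s = 60 / hr, rmssd_s = 0.03,
                     sdnn_s = 0.03, n_beats = 36)
  rel <- relabel_by_baseline_hr(res, summ)
  m <- tapply(hr, rel$assignments, mean)
  expect_true(all(diff(m) > 0))
  expect_equal(sum(rel$sizes), 51)
})

test_that("WSS is non-increasing across Lloyd iterations", {
  set.seed(12)
  pts <- matrix(rnorm(80), 40, 2)
  centers <- pts[sample(40, 3), ]
  wss_seq <- numeric(0)
  for (it in 1:15) {
    d2 <- sapply(1:3, function(j)
      rowSums((pts - matrix(centers[j, ], 40, 2, byrow = TRUE))^2))
    a <- max.col(-d2, ties.method = "first")
    wss_seq <- c(wss_seq, sum(d2[cbind(1:40, a)]))
    for (j in 1:3) centers[j, ] <- colMeans(pts[a == j, , drop = FALSE])
  }
  expect_true(all(diff(wss_seq) <= 1e-12))
})

test_that("cluster characterisation grades questionnaires and excludes sparse items", {
  cfg <- default_sim_config(n_fm = 51, n_control = 2, master_seed = 41)
  coh <- generate_cohort(cfg)
  fm <- coh$subjects[coh$subjects$group == "FM", ]
  res <- structure(list(assignments = fm$true_cluster, k = 3,
                        sizes = as.integer(table(fm$true_cluster)),
                        subject_id = fm$subject_id,
                        centers = matrix(0, 3, 1), wss = 0),
                   class = "hrv_kmeans")
  chr <- characterize_clusters(coh$subjects, res, coh$truth_hrv, coh$nrs)
  # items 3 and 4 carry ~40% missingness and must be excluded
  expect_true(all(c("fiq_item3", "fiq_item4") %in% chr$excluded_items))
  expect_false("fiq_item9" %in% chr$excluded_items)
  # anxiety grading (cluster 3 > 1) is detected by Tukey on true labels
  tk <- chr$questionnaires$fiq_item9$tukey
  expect_lt(tk$p_adj[tk$pair == "3-1"], 0.05)
  # GLS trajectory fits exist for the HRV outcomes and NRS
  expect_true(all(c("hr_bpm", "nrs_pain", "nrs_stress") %in% names(chr$gls)))
  cf <- chr$gls$hr_bpm$coefficients
  expect_true(any(grepl("groupc2:timestress2|groupc3:timestress2", cf$term)))
})
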