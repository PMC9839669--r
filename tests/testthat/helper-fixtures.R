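# Shared fixtures, built in code at test time.

# A clean synthetic recording plus its contaminated version and truth beats.
make_recording <- function(seed = 1, dur = 120, fs = 1000,
                           cfg = default_sim_config()) {
  sched <- phase_schedule(phase_dur_s = dur / 5, baseline_dur_s = dur / 40,
                          analysis_offset_s = 2, analysis_dur_s = dur / 10)
  profile <- autonomic_profile(c(70, 72, 82, 74, 80, 72), 0.028, 0.030)
  rr <- generate_rr_trajectory(profile, sched, seed)
  clean <- synthesize_ecg(rr, fs = fs, duration_s = dur)
  list(rr = rr, clean = clean,
       dirty = contaminate(clean, cfg, seed + 100), sched = sched)
}

# Match detected beats to truth within a tolerance; returns sens/ppv/median
# absolute error (s).
match_beats <- function(detected, truth, tol = 0.05) {
  used <- rep(FALSE, length(detected))
  tp <- 0; errs <- numeric(0)
  for (b in truth) {
    d <- abs(detected - b)
    j <- which.min(d)
    if (length(j) && d[j] <= tol && !used[j]) {
      tp <- tp + 1; used[j] <- TRUE; errs <- c(errs, d[j])
    }
  }
  list(sens = tp / length(truth), ppv = tp / length(detected),
       med_err = stats::median(errs))
}

# rr_series straight from a vector of intervals (accepted).
rr_from_intervals <- function(x, t0 = 0) {
  beats_to_rr(t0 + cumsum(c(0, x)))
}

# Brute-force k-means oracle, 1-D: optimal clusters are contiguous in sorted
# order, so enumerate all split points.
brute_kmeans_1d <- function(x, k) {
  xs <- sort(x); n <- length(xs)
  best <- Inf
  for (sp in utils::combn(n - 1, k - 1, simplify = FALSE)) {
    bnd <- c(0, sp, n); w <- 0
    for (j in seq_len(k)) {
      seg <- xs[(bnd[j] + 1):bnd[j + 1]]
      w <- w + sum((seg - mean(seg))^2)
    }
    if (w < best) best <- w
  }
  best
}

# Brute-force oracle, any dimension: enumerate all label assignments.
brute_kmeans_nd <- function(X, k) {
  n <- nrow(X); best <- Inf
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  for (i in seq_len(nrow(grid))) {
    a <- grid[i, ]
    if (length(unique(a)) < k) next
    w <- 0
    for (j in seq_len(k)) {
      S <- X[a == j, , drop = FALSE]
      w <- w + sum(scale(S, scale = FALSE)^2)
    }
    if (w < best) best <- w
  }
  best
}

# Null long-format repeated-measures data with exchangeable correlation rho
# and an optional FM:stress2 interaction delta.
simulate_long_null <- function(seed, n_fm = 51, n_control = 31, rho = 0.3,
                               sigma = 4, delta_s2 = 0) {
  set.seed(seed)
  n <- n_fm + n_control
  ids <- sprintf("S%03d", seq_len(n))
  grp <- c(rep("FM", n_fm), rep("control", n_control))
  base <- stats::rnorm(n, ifelse(grp == "FM", 72, 64.5), 8)
  tl <- c("relax1", "stress1", "relax2", "stress2", "relax3")
  te <- c(0, 11.5, 2.5, 11.7, 0.6)
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    u <- stats::rnorm(1, 0, sqrt(rho) * sigma)
    e <- stats::rnorm(5, 0, sqrt(1 - rho) * sigma)
    y <- 0.9 * base[i] + te + u + e +
      ifelse(grp[i] == "FM" & tl == "stress2", delta_s2, 0)
    data.frame(subject_id = ids[i], group = grp[i],
               time = factor(tl, levels = tl), y = y, baseline = base[i],
               stringsAsFactors = FALSE)
  }))
  rows$group <- factor(rows$group, levels = c("control", "FM"))
  rows
}
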