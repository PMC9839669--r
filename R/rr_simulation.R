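# Ground-truth RR tachogram generation. The instantaneous RR interval is a
# phase-piecewise mean (linear 10-s ramps at phase boundaries) plus one
# sinusoidal respiratory component plus AR(1) noise. The two noise
# components are solved per subject so that the expected short-window RMSSD
# and SDNN match the profile's short-term and overall variability
# amplitudes.

#' Construct an autonomic profile
#'
#' The per-subject ground truth for RR dynamics: mean heart rate for each
#' analysis window (baseline + 5 phases), short-term (RMSSD-driving) and
#' overall (SDNN-driving) variability amplitudes, and the respiratory
#' modulation frequency.
#'
#' @param hr_bpm numeric length-6 vector of mean HR (bpm), ordered
#'   baseline, relax1, stress1, relax2, stress2, relax3.
#' @param rmssd_s target short-term variability amplitude (s).
#' @param sdnn_s target overall variability amplitude (s).
#' @param resp_freq_hz respiratory modulation frequency (Hz).
#' @param stress_var_scale multiplicative scaling of variability during
#'   stress phases.
#' @return an object of class `autonomic_profile`.
#' @export
autonomic_profile <- function(hr_bpm, rmssd_s, sdnn_s,
                              resp_freq_hz = 0.25, stress_var_scale = 1) {
  stopifnot(length(hr_bpm) == 6, all(hr_bpm >= 40 & hr_bpm <= 180),
            rmssd_s >= 0, sdnn_s >= 0, resp_freq_hz > 0,
            stress_var_scale >= 0)
  names(hr_bpm) <- WINDOW_LABELS
  structure(list(hr_bpm = hr_bpm, rmssd_s = rmssd_s, sdnn_s = sdnn_s,
                 resp_freq_hz = resp_freq_hz,
                 stress_var_scale = stress_var_scale),
            class = "autonomic_profile")
}

# Solve sinusoid amplitude a, AR(1) coefficient phi and innovation SD so
# that the marginal SD matches `sdnn` and the RMS successive difference
# matches `rmssd` at mean beat spacing `rr_bar`. A finite-sample correction
# inflates the AR variance so that the *sample* SD over a window of
# `n_window` beats is unbiased (short AR(1) windows under-estimate the
# marginal SD because the window mean absorbs slow fluctuation).
solve_rr_noise <- function(rmssd, sdnn, rr_bar, resp_freq,
                           resp_fraction = 0.25, n_window = 36) {
  if (sdnn <= 0 || rmssd <= 0) {
    return(list(a = 0, phi = 0, sd_innov = 0))
  }
  s2 <- sdnn^2
  r2 <- rmssd^2
  sin2 <- sin(pi * resp_freq * rr_bar)^2
  a2 <- 2 * resp_fraction * s2
  # respiration must not exhaust the RMSSD budget
  if (2 * a2 * sin2 > 0.5 * r2) a2 <- 0.25 * r2 / sin2
  rmssd_n2 <- max(r2 - 2 * a2 * sin2, 1e-12)
  var_n <- max(s2 - a2 / 2, rmssd_n2 / 4 + 1e-12)
  clamp_phi <- function(p) min(max(p, -0.5), 0.9)
  phi <- clamp_phi(1 - rmssd_n2 / (2 * var_n))
  # fixed point on the short-window sample-variance correction; the
  # correction is floored so strongly correlated draws cannot run away
  for (i in 1:3) {
    corr <- max(ar1_sample_var_factor(phi, n_window), 0.6)
    var_adj <- var_n / corr
    phi <- clamp_phi(1 - rmssd_n2 / (2 * var_adj))
  }
  var_adj <- var_n / max(ar1_sample_var_factor(phi, n_window), 0.6)
  # c4-style correction: E[sample SD] ~ sigma * (1 - 1/(4n))
  var_adj <- var_adj / (1 - 1 / (4 * n_window))^2
  list(a = sqrt(a2), phi = phi, sd_innov = sqrt(var_adj * (1 - phi^2)))
}

# E[sample variance] / marginal variance for AR(1) over n observations.
ar1_sample_var_factor <- function(phi, n) {
  if (n < 2) return(1)
  k <- seq_len(n - 1)
  1 - 2 * sum((n - k) * phi^k) / (n * (n - 1))
}

# Piecewise-linear mean RR curve over the recording, with `ramp_s` linear
# transitions at window boundaries.
mean_rr_fun <- function(profile, schedule, ramp_s = 10) {
  w <- schedule$windows
  base_dur <- w$win_dur_s[w$label == "baseline"]
  ph <- schedule$phases
  # segments: baseline [0, base_dur), then phases (relax1 truncated at base_dur)
  seg_start <- c(0, base_dur, ph$start_s[-1])
  seg_end <- c(base_dur, ph$end_s[1], ph$end_s[-1])
  seg_val <- 60 / profile$hr_bpm[c("baseline", PHASE_LABELS)]
  kx <- numeric(0); ky <- numeric(0)
  for (i in seq_along(seg_val)) {
    ramp_end <- min(seg_start[i] + ramp_s, seg_end[i])
    kx <- c(kx, ramp_end, seg_end[i])
    ky <- c(ky, seg_val[i], seg_val[i])
  }
  kx[1] <- 0  # no ramp into the first segment
  function(t) stats::approx(kx, ky, xout = t, rule = 2)$y
}

# Variability weight over time: 1 in relaxation, stress_var_scale in stress
# phases, with the same ramps.
var_weight_fun <- function(profile, schedule, ramp_s = 10) {
  s <- profile$stress_var_scale
  if (s == 1) return(function(t) rep(1, length(t)))
  ph <- schedule$phases
  vals <- ifelse(grepl("^stress", ph$label), s, 1)
  kx <- numeric(0); ky <- numeric(0)
  for (i in seq_len(nrow(ph))) {
    kx <- c(kx, min(ph$start_s[i] + ramp_s, ph$end_s[i]), ph$end_s[i])
    ky <- c(ky, vals[i], vals[i])
  }
  kx[1] <- 0
  function(t) stats::approx(kx, ky, xout = t, rule = 2)$y
}

#' Generate a ground-truth RR tachogram
#'
#' Beats are laid down sequentially: each interval is the phase-dependent
#' mean RR at the current time plus a sinusoidal respiratory component and
#' AR(1) noise, with variability optionally damped during stress phases.
#'
#' @param profile an [autonomic_profile()].
#' @param schedule a [phase_schedule()].
#' @param rng_seed integer seed; identical seeds give identical beat times.
#' @param ramp_s phase-transition ramp in seconds.
#' @return an `rr_series` (see [beats_to_rr()]) whose `beat_times_s`
#'   attribute covers the full recording.
#' @export
generate_rr_trajectory <- function(profile, schedule, rng_seed, ramp_s = 10) {
  stopifnot(inherits(profile, "autonomic_profile"),
            inherits(schedule, "phase_schedule"))
  if (any(profile$hr_bpm <= 0)) stop("degenerate profile: non-positive mean HR")
  total <- schedule$total_dur_s
  # noise components are calibrated at the baseline window's beat spacing
  rr_bar <- 60 / profile$hr_bpm[["baseline"]]
  base_w <- schedule$windows[schedule$windows$label == "baseline", ]
  n_base <- max(round(base_w$win_dur_s / rr_bar), 5)
  noise <- solve_rr_noise(profile$rmssd_s, profile$sdnn_s, rr_bar,
                          profile$resp_freq_hz, n_window = n_base)
  mfun <- mean_rr_fun(profile, schedule, ramp_s)
  wfun <- var_weight_fun(profile, schedule, ramp_s)
  # precompute mean/weight curves on a fine grid; per-beat lookup is then
  # O(1) instead of an approx() call per beat
  dt_grid <- 0.125
  grid <- seq(0, total + dt_grid, by = dt_grid)
  mv <- mfun(grid)
  wv <- wfun(grid)
  n_max <- ceiling(total / 0.3) + 10
  with_seed(rng_seed, {
    innov <- stats::rnorm(n_max, 0, noise$sd_innov)
    phase0 <- stats::runif(1, 0, 2 * pi)
    beats <- numeric(n_max)
    t <- 0; e <- if (noise$sd_innov > 0)
      stats::rnorm(1, 0, noise$sd_innov / sqrt(1 - noise$phi^2)) else 0
    i <- 0
    omega <- 2 * pi * profile$resp_freq_hz
    a <- noise$a; phi <- noise$phi
    while (t < total && i < n_max) {
      i <- i + 1
      gi <- t / dt_grid
      g0 <- floor(gi)
      fr <- gi - g0
      m <- mv[g0 + 1] * (1 - fr) + mv[g0 + 2] * fr
      w <- wv[g0 + 1] * (1 - fr) + wv[g0 + 2] * fr
      rr <- m + w * (a * sin(omega * t + phase0) + e)
      rr <- max(rr, 0.25)
      t <- t + rr
      beats[i] <- t
      e <- phi * e + innov[i]
    }
    beats <- beats[seq_len(i)]
    beats <- beats[beats <= total]
    beats_to_rr(beats)
  })
}
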