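test_that("detrend removes the mean and optionally a linear trend", {
  w <- waveform(rep(5, 100), 100)
  expect_true(all(abs(detrend(w)$samples) < 1e-12))
  w2 <- waveform(c(1, -1), 100)
  expect_equal(detrend(w2)$samples, c(1, -1))
  ramp <- waveform(seq(0, 1, length.out = 1000), 100)
  res <- detrend(ramp, linear = TRUE)$samples
  slope <- stats::coef(stats::lm(res ~ seq_along(res)))[2]
  expect_lt(abs(slope), 1e-9)
  expect_error(detrend(waveform(1, 100)))
})

test_that("noise-peak detection flags a mains tone but not white spectra", {
  fs <- 1000; n <- 60 * fs
  set.seed(1)
  tt <- (seq_len(n) - 1) / fs
  tone <- waveform(sin(2 * pi * 50 * tt) + 0.05 * rnorm(n), fs)
  spec <- hrvreact:::periodogram_est(tone)
  flags <- detect_noise_peaks(spec, c(50, 100, 150), threshold = 3)
  expect_equal(flags$f0, 50)
  expect_equal(c(flags$lo, flags$hi), c(49.5, 50.5))
  white <- waveform(rnorm(n), fs)
  expect_equal(nrow(detect_noise_peaks(hrvreact:::periodogram_est(white))), 0)
  # infinite threshold flags nothing
  expect_equal(nrow(detect_noise_peaks(spec, threshold = Inf)), 0)
  # beyond-Nyquist candidate skipped with warning
  expect_warning(detect_noise_peaks(spec, candidate_f0s = c(50, 600)))
})

test_that("spectral flattening equalises band power and conserves the rest", {
  fs <- 1000; n <- 30 * fs
  set.seed(2)
  tt <- (seq_len(n) - 1) / fs
  w <- waveform(0.8 * sin(2 * pi * 50 * tt) + rnorm(n, 0, 0.3), fs)
  out <- flatten_noise_band(w, c(49.5, 50.5))
  bp <- function(x, lo, hi) hrvreact:::band_power(x, fs, lo, hi)
  inb <- bp(out$samples, 49.5, 50.5)
  flank <- (bp(out$samples, 49, 49.5) + bp(out$samples, 50.5, 51))
  # mean power per Hz in band vs flanks (both spans are 1 Hz total)
  expect_lt(abs(inb / flank - 1), 0.05)
  # out-of-band power conserved to 1e-6 relative
  expect_lt(abs(bp(out$samples, 1, 45) / bp(w$samples, 1, 45) - 1), 1e-6)
  expect_lt(abs(bp(out$samples, 55, 200) / bp(w$samples, 55, 200) - 1), 1e-6)
  # near-idempotent: band power moves < 5% on reapplication
  out2 <- flatten_noise_band(out, c(49.5, 50.5))
  expect_lt(abs(bp(out2$samples, 49.5, 50.5) / inb - 1), 0.05)
  # a quiet band with equal flanks is (nearly) untouched
  wq <- waveform(rnorm(n, 0, 0.3), fs)
  outq <- flatten_noise_band(wq, c(49.5, 50.5))
  expect_lt(sqrt(mean((outq$samples - wq$samples)^2)) / stats::sd(wq$samples), 0.05)
  expect_error(flatten_noise_band(w, c(-1, 0.5)))
  expect_error(flatten_noise_band(w, c(490, 510)))
})

test_that("QRS bandpass passes 25 Hz, attenuates 50 Hz, removes DC", {
  fs <- 1000; n <- 20 * fs
  tt <- (seq_len(n) - 1) / fs
  amp_out <- function(f) {
    w <- waveform(sin(2 * pi * f * tt), fs)
    y <- bandpass_qrs(w)$samples[(5 * fs):(15 * fs)]
    max(abs(y))
  }
  expect_gt(amp_out(25), 0.9)
  expect_lt(amp_out(25), 1.001)
  expect_lt(amp_out(50), amp_out(25))
  dc <- bandpass_qrs(waveform(rep(1, n), fs))$samples
  expect_lt(abs(mean(dc)), 1e-3)
  expect_error(bandpass_qrs(waveform(rnorm(100), 70)))
})

test_that("PCA enhancement preserves clean QRS trains and improves band SNR", {
  rec <- make_recording(seed = 3)
  clean_bp <- bandpass_qrs(detrend(rec$clean))
  iso <- isolate_ecg_pca(clean_bp, embed_dim = 25)
  expect_gt(stats::cor(iso$samples, clean_bp$samples), 0.95)
  # 0 dB QRS-band noise: apply the learned matched filter to the signal and
  # noise components separately and compare in-band SNR before vs after
  dirty_bp <- bandpass_qrs(detrend(rec$dirty))
  iso2 <- isolate_ecg_pca(dirty_bp)
  kern <- attr(iso2, "kernel")
  noise_bp <- dirty_bp$samples - clean_bp$samples
  fk <- function(x) {
    y <- stats::filter(x, kern, sides = 2)
    y[is.na(y)] <- 0
    as.numeric(y)
  }
  bp <- function(x) hrvreact:::band_power(x, 1000, 10, 40)
  snr_in <- bp(clean_bp$samples) / bp(noise_bp)
  snr_out <- bp(fk(clean_bp$samples)) / bp(fk(noise_bp))
  expect_gt(snr_out, snr_in)
  # pure white noise: no error, variance contracts
  wn <- waveform(rnorm(20000), 1000)
  expect_lte(stats::var(isolate_ecg_pca(wn)$samples), stats::var(wn$samples))
  expect_error(isolate_ecg_pca(waveform(rnorm(10), 1000), embed_dim = 50))
})

test_that("synthesized templates land on beats, scale linearly, handle empties", {
  w <- synthesize_ecg(c(1, 2, 3), fs = 1000, duration_s = 4)
  for (b in c(1, 2, 3)) {
    seg <- w$samples[(b * 1000 - 99):(b * 1000 + 101)]
    expect_lte(abs(which.max(seg) - 100), 1)
  }
  w2 <- synthesize_ecg(c(1, 2, 3), fs = 1000, duration_s = 4, amp_mv = 2)
  expect_equal(w2$samples, 2 * w$samples)
  empty <- synthesize_ecg(numeric(0), fs = 1000, duration_s = 1)
  expect_true(all(empty$samples == 0))
  expect_error(synthesize_ecg(c(1, 1.01), fs = 1000))  # spacing < template width
})

test_that("contamination is seeded, reduces to identity, and places mains power", {
  rec <- make_recording(seed = 4)
  cfg <- default_sim_config()
  d1 <- contaminate(rec$clean, cfg, 9)
  d2 <- contaminate(rec$clean, cfg, 9)
  expect_identical(d1$samples, d2$samples)
  cfg0 <- default_sim_config(emg_snr_db = Inf, mains_amp_mv = 0, drift_amp_mv = 0)
  expect_equal(contaminate(rec$clean, cfg0, 1)$samples, rec$clean$samples)
  # pure 50 Hz mains of amplitude a carries ~a^2/2 power at 50 Hz
  cfgm <- default_sim_config(emg_snr_db = Inf, mains_amp_mv = 0.5,
                             mains_harmonics = 0L, drift_amp_mv = 0)
  flat <- waveform(rep(0, 60000), 1000)
  m <- contaminate(flat, cfgm, 2)
  p50 <- hrvreact:::band_power(m$samples, 1000, 49.5, 50.5)
  expect_lt(abs(p50 / (0.5^2 / 2) - 1), 0.02)
})

test_that("QRS detection on a clean minute-long 60-bpm ECG is near exact", {
  beats <- seq(1, 59, by = 1)
  w <- synthesize_ecg(beats, fs = 1000, duration_s = 60)
  bp <- isolate_ecg_pca(bandpass_qrs(detrend(w)))
  det <- detect_qrs(bp)
  m <- match_beats(det, beats, tol = 0.05)
  expect_gte(m$sens, 59 / 60)
  expect_gte(m$ppv, 0.98)
  expect_lt(m$med_err, 0.005)
  # zero-phase chain: beat shift under 2 ms
  expect_lt(m$med_err, 0.002)
})

test_that("flat signals and refractory pairs behave as specified", {
  flat <- waveform(rep(0, 10000), 1000)
  expect_warning(det <- detect_qrs(flat))
  expect_length(det, 0)
  # two template beats 100 ms apart: one detection (250-ms refractory)
  w <- synthesize_ecg(c(1, 1.1), fs = 1000, duration_s = 3)
  cfg <- extract_config(rhythm_correct = FALSE)
  det2 <- detect_qrs(w, cfg)
  expect_equal(length(det2), 1)
})

test_that("beats_to_rr computes successive differences and rejects disorder", {
  rr <- beats_to_rr(c(1, 2, 3.5))
  expect_equal(rr$intervals_s, c(1, 1.5))
  expect_equal(rr$end_times_s, c(2, 3.5))
  expect_length(beats_to_rr(c(5))$intervals_s, 0)
  expect_error(beats_to_rr(c(1, 0.5)))
})

test_that("clean_rr applies range, median, and adaptive rules", {
  x <- rep(0.8, 30)
  rr <- rr_from_intervals(x)
  expect_true(all(clean_rr(rr)$flag == "ok"))
  x2 <- x; x2[15] <- 0.1
  rr2 <- clean_rr(rr_from_intervals(x2))
  expect_equal(which(rr2$flag == "rejected"), 15)
  # rules disabled: output equals input flags
  off <- extract_config(rr_min_s = -Inf, rr_max_s = Inf,
                        rr_median_tol = Inf, rr_mad_k = Inf)
  expect_true(all(clean_rr(rr_from_intervals(x2), off)$flag == "ok"))
  # adaptive rule catches a displacement too small for the 30% rule
  set.seed(8)
  x3 <- 0.8 + rnorm(300, 0, 0.01)
  x3[100] <- x3[100] + 0.12; x3[101] <- x3[101] - 0.12   # 15% shift
  fl <- clean_rr(rr_from_intervals(x3))$flag
  expect_true(all(fl[c(100, 101)] == "rejected"))
})

test_that("channel selection prefers the ECG-bearing channel", {
  rec <- make_recording(seed = 6)
  set.seed(6)
  noisech <- waveform(rnorm(length(rec$dirty$samples), 0, 1), rec$dirty$fs)
  expect_equal(select_channel(list(rec$dirty, noisech)), 1L)
  expect_equal(select_channel(list(noisech, rec$dirty)), 2L)
  expect_equal(select_channel(list(rec$dirty)), 1L)
  expect_equal(select_channel(list(rec$dirty, rec$dirty)), 1L)  # tie -> lower index
})
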