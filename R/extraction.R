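# ECG recovery from an EMG-contaminated single-channel waveform:
# detrend -> powerline spectral flattening -> 10-40 Hz Butterworth bandpass
# -> time-delay-embedding PCA enhancement -> QRS detection -> RR intervals.

#' Default extraction configuration
#'
#' All thresholds of the extraction chain in one list. `bands = NULL`
#' selects automatic powerline-band detection at the candidate
#' fundamentals; supply explicit 1-Hz band centres to override (the manual
#' analogue of visual spectrum inspection).
#'
#' @param ... overrides of the listed defaults.
#' @return a list of class `extract_config`.
#' @export
extract_config <- function(...) {
  cfg <- list(
    candidate_f0s = c(50, 100, 150),  # mains fundamental and harmonics (Hz)
    noise_peak_threshold = 3,         # band/flank power ratio for flagging
    bands = NULL,                     # explicit band centres, or NULL = auto
    bp_low = 10, bp_high = 40, bp_order = 3,
    zero_phase = TRUE,
    linear_detrend = FALSE,
    embed_ms = 80,                    # PCA time-delay embedding span
    integrate_ms = 150,               # moving-window integration span
    det_c = 0.4,                      # threshold multiple of running median peak
    refractory_ms = 250,
    rhythm_correct = TRUE,            # short/long interval repair passes
    rr_min_s = 0.3, rr_max_s = 2.0,   # clean_rr absolute limits
    rr_median_window = 5, rr_median_tol = 0.3,
    rr_mad_k = 3, rr_mad_floor_s = 0.01)  # adaptive local-variability rule
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  class(cfg) <- "extract_config"
  cfg
}

#' Detrend a waveform to zero mean
#'
#' Removes the mean; optionally also a least-squares linear trend.
#'
#' @param wave a `waveform`.
#' @param linear if `TRUE`, remove a fitted linear trend as well.
#' @return a detrended `waveform`.
#' @export
detrend <- function(wave, linear = FALSE) {
  stopifnot(inherits(wave, "waveform"))
  x <- wave$samples
  if (length(x) < 2) stop("detrend needs at least 2 samples")
  if (linear) {
    t <- seq_along(x)
    x <- stats::residuals(stats::lm.fit(cbind(1, t), x))
  } else {
    x <- x - mean(x)
  }
  waveform(as.numeric(x), wave$fs, wave$channel_label, wave$start_time_s)
}

#' Detect powerline noise peaks in a power spectrum
#'
#' A candidate frequency is flagged when the mean power in its 1-Hz band
#' \[f - 0.5, f + 0.5) exceeds `threshold` times the mean power of the two
#' flanking 0.5-Hz bands. Candidates beyond Nyquist are skipped with a
#' warning.
#'
#' @param spec a `spectral_estimate` (e.g. from the raw periodogram) or a
#'   list with `frequencies` and `power`.
#' @param candidate_f0s candidate centre frequencies (Hz).
#' @param threshold band/flank mean-power ratio above which a candidate is
#'   flagged.
#' @return data.frame of flagged bands with columns `f0`, `lo`, `hi`.
#' @export
detect_noise_peaks <- function(spec, candidate_f0s = c(50, 100, 150),
                               threshold = 3) {
  f <- spec$frequencies; p <- spec$power
  nyq <- max(f)
  out <- list()
  for (f0 in candidate_f0s) {
    if (f0 + 1 > nyq) {
      warning("candidate ", f0, " Hz beyond Nyquist; skipped")
      next
    }
    inb <- f >= f0 - 0.5 & f < f0 + 0.5
    flank <- (f >= f0 - 1 & f < f0 - 0.5) | (f >= f0 + 0.5 & f < f0 + 1)
    if (!any(inb) || !any(flank)) next
    if (mean(p[inb]) > threshold * mean(p[flank]))
      out[[length(out) + 1]] <- data.frame(f0 = f0, lo = f0 - 0.5, hi = f0 + 0.5)
  }
  if (!length(out)) return(data.frame(f0 = numeric(), lo = numeric(), hi = numeric()))
  do.call(rbind, out)
}

#' Flatten a noisy 1-Hz spectral band
#'
#' Frequency-domain interpolation: the magnitudes of DFT bins inside the
#' band are rescaled so the band's mean power equals the mean power of the
#' 0.5-Hz flanks immediately above and below; phases are preserved and
#' conjugate symmetry is maintained, so the output is real and power
#' outside the treated band is untouched.
#'
#' @param wave a `waveform`.
#' @param band numeric length-2 `c(lo, hi)` in Hz, strictly inside
#'   (0, Nyquist).
#' @return a `waveform` with the band flattened.
#' @export
flatten_noise_band <- function(wave, band) {
  stopifnot(inherits(wave, "waveform"), length(band) == 2, band[1] < band[2])
  fs <- wave$fs
  n <- length(wave$samples)
  if (band[1] <= 0 || band[2] >= fs / 2)
    stop("band must lie strictly inside (0, Nyquist)")
  X <- stats::fft(wave$samples)
  f <- (seq_len(n) - 1) * fs / n
  fmir <- pmin(f, fs - f)   # mirrored frequency of each bin
  inb <- fmir >= band[1] & fmir < band[2]
  flank <- (fmir >= band[1] - 0.5 & fmir < band[1]) |
           (fmir >= band[2] & fmir < band[2] + 0.5)
  band_mean <- mean(Mod(X[inb])^2)
  flank_mean <- mean(Mod(X[flank])^2)
  if (band_mean > 0) {
    X[inb] <- X[inb] * sqrt(flank_mean / band_mean)
  }
  waveform(Re(stats::fft(X, inverse = TRUE) / n), fs,
           wave$channel_label, wave$start_time_s)
}

#' QRS-band Butterworth bandpass
#'
#' Third-order Butterworth bandpass to 10-40 Hz (the band containing most
#' QRS energy), applied forward-backward by default so beat times are not
#' lag-shifted.
#'
#' @param wave a `waveform` with `fs > 80` Hz.
#' @param low,high corner frequencies (Hz).
#' @param order filter order.
#' @param zero_phase forward-backward filtering if `TRUE` (default);
#'   single-pass causal otherwise.
#' @return a filtered `waveform`.
#' @export
bandpass_qrs <- function(wave, low = 10, high = 40, order = 3,
                         zero_phase = TRUE) {
  stopifnot(inherits(wave, "waveform"))
  if (wave$fs <= 2 * high) stop("sampling rate must exceed twice the upper corner")
  bf <- signal::butter(order, c(low, high) / (wave$fs / 2), type = "pass")
  x <- if (zero_phase) signal::filtfilt(bf, wave$samples)
       else as.numeric(signal::filter(bf, wave$samples))
  waveform(x, wave$fs, wave$channel_label, wave$start_time_s)
}

#' Single-channel ECG enhancement by time-delay-embedding PCA
#'
#' The filtered signal is embedded with unit lag into `embed_dim`
#' dimensions; the embedding covariance (a Toeplitz matrix of the signal's
#' autocovariance) is eigendecomposed and the rank-1 approximation along
#' the first principal component is reconstructed by diagonal averaging.
#' For a long signal this reduces to zero-phase filtering with the
#' autocorrelation of the first eigenvector, i.e. a data-learned matched
#' filter for the dominant (QRS) waveform. The sign is chosen so dominant
#' peaks are positive.
#'
#' @param wave a `waveform` (normally the bandpassed signal).
#' @param embed_dim embedding dimension in samples; default 80 ms worth.
#' @return an enhanced `waveform`.
#' @export
isolate_ecg_pca <- function(wave, embed_dim = NULL) {
  stopifnot(inherits(wave, "waveform"))
  if (is.null(embed_dim)) embed_dim <- max(round(0.080 * wave$fs), 2)
  if (embed_dim < 2) stop("embed_dim must be at least 2")
  x <- wave$samples
  if (length(x) < embed_dim) stop("signal shorter than the embedding dimension")
  ac <- stats::acf(x, lag.max = embed_dim - 1, type = "covariance",
                   plot = FALSE, demean = FALSE)$acf[, 1, 1]
  v1 <- eigen(stats::toeplitz(ac), symmetric = TRUE)$vectors[, 1]
  kern <- stats::convolve(v1, v1, type = "open") / embed_dim
  rec <- stats::filter(x, kern, sides = 2)
  rec[is.na(rec)] <- 0
  rec <- as.numeric(rec)
  if (max(rec) < -min(rec)) rec <- -rec
  out <- waveform(rec, wave$fs, wave$channel_label, wave$start_time_s)
  attr(out, "kernel") <- kern   # the learned zero-phase matched filter
  out
}

#' Multichannel ECG isolation by cross-channel PCA
#'
#' Alternative mode: projects multiple simultaneously recorded channels
#' onto their first principal component.
#'
#' @param waves list of `waveform`s with equal length and sampling rate.
#' @return a single `waveform` (the first principal-component score).
#' @export
isolate_ecg_pca_multichannel <- function(waves) {
  stopifnot(length(waves) >= 2)
  M <- sapply(waves, function(w) w$samples)
  M <- scale(M, center = TRUE, scale = FALSE)
  v1 <- eigen(crossprod(M) / nrow(M), symmetric = TRUE)$vectors[, 1]
  sc <- as.numeric(M %*% v1)
  if (max(sc) < -min(sc)) sc <- -sc
  waveform(sc, waves[[1]]$fs, "PCA-MULTI", waves[[1]]$start_time_s)
}

# Running median of the inter-beat intervals (index space), window 15.
running_median_rr <- function(bt) {
  rr <- diff(bt)
  if (length(rr) < 5) return(rep(stats::median(rr), length(rr)))
  k <- min(15, 2 * floor(length(rr) / 2) - 1)
  as.numeric(stats::runmed(rr, k = k))
}

#' Detect QRS complexes
#'
#' Energy detector: the enhanced signal is squared and moving-window
#' integrated (150 ms); integrated local maxima are accepted when they
#' exceed `det_c` times the running median of recent accepted peak heights,
#' under a 250-ms refractory period. Optional rhythm-correction passes
#' remove spurious detections that create intervals shorter than 0.7 times
#' the local median RR (keeping the stronger peak) and search long gaps
#' (over 1.6 times the local median) for a missed beat. The beat time is
#' the local maximum of the enhanced signal near each accepted detection.
#'
#' @param wave the isolated, bandpassed `waveform`.
#' @param cfg an [extract_config()].
#' @return numeric vector of strictly increasing beat times (s); empty
#'   with a warning when nothing crosses the threshold.
#' @export
detect_qrs <- function(wave, cfg = extract_config()) {
  stopifnot(inherits(wave, "waveform"))
  fs <- wave$fs
  rec <- wave$samples
  n <- length(rec)
  iw <- 2 * floor(cfg$integrate_ms / 1000 * fs / 2) + 1
  intg <- stats::filter(rec^2, rep(1 / iw, iw), sides = 2)
  intg[is.na(intg)] <- 0
  intg <- as.numeric(intg)
  cand <- which(diff(sign(diff(intg))) == -2) + 1
  if (!length(cand) || all(intg[cand] <= 0)) {
    warning("no QRS candidates above threshold")
    return(numeric(0))
  }
  refr <- round(cfg$refractory_ms / 1000 * fs)
  med0 <- stats::median(intg[cand][intg[cand] > stats::quantile(intg[cand], 0.7)])
  recent <- rep(med0, 8)
  det <- integer(0); last <- -Inf
  for (i in cand) {
    h <- intg[i]
    if (h > cfg$det_c * stats::median(recent)) {
      if ((i - last) < refr) {
        if (h > intg[last]) {   # stronger peak inside refractory wins
          det[length(det)] <- i; last <- i; recent[length(recent)] <- h
        }
      } else {
        det <- c(det, i); last <- i
        recent <- c(recent[-1], h)
      }
    }
  }
  if (!length(det)) {
    warning("no QRS detections above threshold")
    return(numeric(0))
  }
  snap <- round(0.075 * fs)
  bt <- vapply(det, function(i) {
    lo <- max(1, i - snap); hi <- min(n, i + snap)
    lo - 1 + which.max(rec[lo:hi])
  }, numeric(1))
  bt <- sort(unique(bt))
  if (cfg$rhythm_correct && length(bt) >= 5) {
    h <- rec[bt]
    repeat {  # drop the weaker endpoint of implausibly short intervals
      rr <- diff(bt)
      if (length(rr) < 3) break
      lm <- running_median_rr(bt)
      bad <- which(rr < 0.7 * lm)
      if (!length(bad)) break
      j <- bad[1]
      drop <- if (h[j] < h[j + 1]) j else j + 1
      bt <- bt[-drop]; h <- h[-drop]
    }
    repeat {  # search long gaps for one missed beat at a time
      rr <- diff(bt)
      lm <- running_median_rr(bt)
      big <- which(rr > 1.6 * lm)
      if (!length(big)) break
      added <- FALSE
      for (j in big) {
        lo <- bt[j] + round(0.2 * fs); hi <- bt[j + 1] - round(0.2 * fs)
        if (hi <= lo) next
        i <- lo - 1 + which.max(rec[lo:hi])
        if (rec[i] > 0.2 * stats::median(h)) {
          bt <- sort(c(bt, i)); h <- rec[bt]; added <- TRUE
          break
        }
      }
      if (!added) break
    }
  }
  (bt - 1) / fs
}

#' Convert beat times to an RR interval series
#'
#' Intervals are successive differences of the beat times, kept in seconds
#' with the end time of each interval recorded; all intervals start out
#' flagged `"ok"`.
#'
#' @param beats numeric vector of strictly ascending beat times (s).
#' @return an object of class `rr_series` with fields `intervals_s`,
#'   `end_times_s`, `flag`, and `beat_times_s`. Fewer than two beats give
#'   an empty series.
#' @export
beats_to_rr <- function(beats) {
  beats <- as.numeric(beats)
  if (length(beats) >= 2 && any(diff(beats) <= 0))
    stop("beat times must be strictly ascending")
  if (length(beats) < 2) {
    return(structure(list(intervals_s = numeric(0), end_times_s = numeric(0),
                          flag = character(0), beat_times_s = beats),
                     class = "rr_series"))
  }
  structure(list(intervals_s = diff(beats), end_times_s = beats[-1],
                 flag = rep("ok", length(beats) - 1), beat_times_s = beats),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("RR series: %d intervals (%d rejected), span %.1f s\n",
              length(x$intervals_s), sum(x$flag == "rejected"),
              if (length(x$end_times_s)) max(x$end_times_s) else 0))
  invisible(x)
}

#' Flag artifactual RR intervals
#'
#' Flags as rejected any interval outside `[rr_min_s, rr_max_s]`, deviating
#' from the running median of its 5-interval neighbourhood by more than
#' `rr_median_tol` (relative), or deviating from that median by more than
#' `rr_mad_k` times the local robust scale of the series (a MAD-based rule
#' that adapts to each recording's own beat-to-beat variability and
#' catches mistimed detections far smaller than the relative rule can).
#' Accepted values are never modified; rejected intervals are excluded
#' from all metrics.
#'
#' @param rr an `rr_series`.
#' @param cfg an [extract_config()]; set `rr_min_s = -Inf`,
#'   `rr_max_s = Inf`, `rr_median_tol = Inf`, `rr_mad_k = Inf` to disable
#'   rules.
#' @return the `rr_series` with updated flags.
#' @export
clean_rr <- function(rr, cfg = extract_config()) {
  stopifnot(inherits(rr, "rr_series"))
  x <- rr$intervals_s
  if (!length(x)) return(rr)
  bad <- x < cfg$rr_min_s | x > cfg$rr_max_s
  if (length(x) >= cfg$rr_median_window) {
    k <- 2 * floor(cfg$rr_median_window / 2) + 1
    med <- as.numeric(stats::runmed(x, k = min(k, 2 * floor(length(x) / 2) - 1)))
    dev <- abs(x - med)
    if (is.finite(cfg$rr_median_tol))
      bad <- bad | dev / med > cfg$rr_median_tol
    if (is.finite(cfg$rr_mad_k)) {
      sigma <- 1.4826 * stats::mad(dev[!bad], center = 0)
      thr <- max(cfg$rr_mad_k * sigma, cfg$rr_mad_floor_s)
      bad <- bad | dev > thr
    }
  }
  rr$flag <- ifelse(bad, "rejected", "ok")
  rr
}

#' Run the full extraction chain on one waveform
#'
#' Detrend, flatten flagged powerline bands, bandpass, PCA-enhance, detect
#' QRS complexes, and convert to a cleaned RR series.
#'
#' @param wave the raw `waveform`.
#' @param cfg an [extract_config()].
#' @return a list with `rr` (cleaned `rr_series`), `beats` (beat times, s),
#'   and `log` (bands flattened, beats found).
#' @export
extract_rr <- function(wave, cfg = extract_config()) {
  w <- detrend(wave, linear = cfg$linear_detrend)
  if (is.null(cfg$bands)) {
    spec <- periodogram_est(w)
    bands <- detect_noise_peaks(spec, cfg$candidate_f0s, cfg$noise_peak_threshold)
  } else {
    bands <- data.frame(f0 = cfg$bands, lo = cfg$bands - 0.5, hi = cfg$bands + 0.5)
  }
  for (i in seq_len(nrow(bands)))
    w <- flatten_noise_band(w, c(bands$lo[i], bands$hi[i]))
  w <- bandpass_qrs(w, cfg$bp_low, cfg$bp_high, cfg$bp_order, cfg$zero_phase)
  w <- isolate_ecg_pca(w, embed_dim = max(round(cfg$embed_ms / 1000 * wave$fs), 2))
  beats <- detect_qrs(w, cfg)
  rr <- clean_rr(beats_to_rr(beats), cfg)
  list(rr = rr, beats = beats,
       log = list(bands_flattened = bands$f0, n_beats = length(beats)))
}

#' Automatic channel selection
#'
#' Scores each channel by the regularity of a trial extraction (the
#' coefficient of variation of accepted RR intervals) and returns the
#' index of the channel with the lowest CV; ties are broken by higher
#' QRS-band SNR, then by lower index. An automated surrogate for visual
#' channel inspection.
#'
#' @param waves list of `waveform`s.
#' @param cfg an [extract_config()].
#' @return integer index into `waves`.
#' @export
select_channel <- function(waves, cfg = extract_config()) {
  stopifnot(length(waves) >= 1)
  if (length(waves) == 1) return(1L)
  score <- t(sapply(waves, function(w) {
    res <- tryCatch(extract_rr(w, cfg), error = function(e) NULL)
    if (is.null(res) || length(res$rr$intervals_s) < 3)
      return(c(cv = Inf, snr = -Inf))
    x <- res$rr$intervals_s[res$rr$flag == "ok"]
    if (length(x) < 3) return(c(cv = Inf, snr = -Inf))
    c(cv = stats::sd(x) / mean(x),
      snr = band_power(w$samples, w$fs, 10, 40) /
        max(band_power(w$samples, w$fs, 40, 70), 1e-12))
  }))
  best_cv <- min(score[, "cv"])
  tied <- which(score[, "cv"] <= best_cv + 1e-12)
  if (length(tied) > 1) tied <- tied[order(-score[tied, "snr"], tied)]
  as.integer(tied[1])
}
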