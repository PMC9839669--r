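# ECG waveform synthesis and contamination to surface-EMG recording
# conditions (EMG-band noise, mains interference, baseline drift).

#' Construct a waveform object
#'
#' @param samples numeric vector of samples (mV).
#' @param fs sampling rate (Hz).
#' @param channel_label channel name.
#' @param start_time_s time of the first sample (s).
#' @return an object of class `waveform`.
#' @export
waveform <- function(samples, fs, channel_label = "EMG-ECG-MIX", start_time_s = 0) {
  stopifnot(is.numeric(samples), fs > 0, all(is.finite(samples)))
  structure(list(samples = as.numeric(samples), fs = fs,
                 channel_label = channel_label, start_time_s = start_time_s),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("Waveform '%s': %d samples @ %g Hz (%.1f s)\n",
              x$channel_label, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

# Ricker (negative second-derivative-of-Gaussian) template, unit peak at 0.
ricker_template <- function(t, width_s) {
  (1 - (t / width_s)^2) * exp(-t^2 / (2 * width_s^2))
}

#' Synthesize an ECG waveform from beat times
#'
#' Places one QRS-like deflection (Ricker template, unit-normalised peak)
#' at each beat time. Linear in the template amplitude.
#'
#' @param rr an `rr_series` (from [generate_rr_trajectory()] or
#'   [beats_to_rr()]) or a numeric vector of beat times (s).
#' @param fs sampling rate (Hz), at least 250.
#' @param duration_s recording length (s); default spans the last beat.
#' @param width_s template shape parameter (s); the visible deflection
#'   spans roughly `6 * width_s` (~80 ms at the default).
#' @param amp_mv peak amplitude (mV).
#' @return a `waveform`.
#' @export
synthesize_ecg <- function(rr, fs = 1000, duration_s = NULL,
                           width_s = 0.012, amp_mv = 1) {
  stopifnot(fs >= 250)
  beats <- if (inherits(rr, "rr_series")) rr$beat_times_s else as.numeric(rr)
  if (length(beats) >= 2 && min(diff(beats)) < 2 * width_s)
    stop("beat spacing shorter than the QRS template width")
  if (is.null(duration_s))
    duration_s <- if (length(beats)) max(beats) + 0.5 else 1
  n <- round(duration_s * fs)
  x <- numeric(n)
  half <- round(4 * width_s * fs)
  for (b in beats) {
    c_idx <- round(b * fs) + 1
    idx <- (c_idx - half):(c_idx + half)
    ok <- idx >= 1 & idx <= n
    x[idx[ok]] <- x[idx[ok]] + amp_mv * ricker_template((idx[ok] - 1) / fs - b, width_s)
  }
  waveform(x, fs, channel_label = "ECG-SYNTH")
}

#' Contaminate a clean ECG to surface-EMG recording conditions
#'
#' Adds band-limited Gaussian EMG noise scaled so the QRS-band (10-40 Hz)
#' signal-to-noise ratio equals `cfg$emg_snr_db`, mains sinusoids at the
#' fundamental and its harmonics, and slow sinusoidal baseline drift.
#' With `emg_snr_db = Inf`, zero mains amplitude and zero drift the output
#' equals the input.
#'
#' @param wave a `waveform`.
#' @param cfg a [default_sim_config()] (fields `emg_snr_db`, `emg_band_hz`,
#'   `mains_freq_hz`, `mains_harmonics`, `mains_amp_mv`, `drift_amp_mv`,
#'   `drift_period_s`).
#' @param rng_seed integer seed; identical seeds give identical noise.
#' @return a contaminated `waveform`.
#' @export
contaminate <- function(wave, cfg = default_sim_config(), rng_seed = 1L) {
  stopifnot(inherits(wave, "waveform"))
  n <- length(wave$samples)
  fs <- wave$fs
  tt <- (seq_len(n) - 1) / fs
  with_seed(rng_seed, {
    out <- wave$samples
    if (is.finite(cfg$emg_snr_db)) {
      wn <- stats::rnorm(n)
      W <- stats::fft(wn)
      f <- (seq_len(n) - 1) * fs / n
      fmir <- pmin(f, fs - f)
      keep <- fmir >= cfg$emg_band_hz[1] & fmir <= cfg$emg_band_hz[2]
      W[!keep] <- 0
      emg <- Re(stats::fft(W, inverse = TRUE) / n)
      sig_p <- band_power(wave$samples, fs, 10, 40)
      noi_p <- band_power(emg, fs, 10, 40)
      if (noi_p > 0 && sig_p > 0) {
        emg <- emg * sqrt(sig_p / noi_p) * 10^(-cfg$emg_snr_db / 20)
        out <- out + emg
      }
    }
    if (cfg$mains_amp_mv > 0) {
      for (h in 0:cfg$mains_harmonics) {
        fh <- cfg$mains_freq_hz * (h + 1)
        if (fh >= fs / 2) next
        amp <- cfg$mains_amp_mv * 0.5^h
        out <- out + amp * sin(2 * pi * fh * tt + stats::runif(1, 0, 2 * pi))
      }
    }
    if (cfg$drift_amp_mv > 0) {
      out <- out + cfg$drift_amp_mv *
        sin(2 * pi * tt / cfg$drift_period_s + stats::runif(1, 0, 2 * pi))
    }
    waveform(out, fs, channel_label = "EMG-ECG-MIX",
             start_time_s = wave$start_time_s)
  })
}
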