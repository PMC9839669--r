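# Time-domain HRV metrics over protocol windows: HR, mean RR, RMSSD, SDNN.
# Internal RR unit is seconds; rejected intervals are excluded from every
# metric and break the successive-difference chain for RMSSD.

accepted <- function(rr) rr$intervals_s[rr$flag == "ok"]

#' Restrict an RR series to a time window
#'
#' Keeps intervals whose end time lies in `[start_s, start_s + dur_s)`;
#' rejected intervals are dropped entirely (they are not carried into the
#' window).
#'
#' @param rr an `rr_series`.
#' @param start_s window start (s).
#' @param dur_s window duration (s), positive.
#' @return an `rr_series` restricted to the window.
#' @export
window_rr <- function(rr, start_s, dur_s) {
  stopifnot(inherits(rr, "rr_series"), dur_s > 0)
  keep <- rr$end_times_s >= start_s & rr$end_times_s < start_s + dur_s &
    rr$flag == "ok"
  # retain original adjacency so RMSSD can honour chain breaks
  idx <- which(keep)
  structure(list(intervals_s = rr$intervals_s[idx],
                 end_times_s = rr$end_times_s[idx],
                 flag = rr$flag[idx],
                 beat_times_s = numeric(0),
                 orig_index = idx),
            class = "rr_series")
}

#' Mean RR interval (s)
#' @param rr an `rr_series`.
#' @return arithmetic mean of accepted intervals, or `NA` when empty.
#' @export
rr_mean <- function(rr) {
  x <- accepted(rr)
  if (!length(x)) return(NA_real_)
  mean(x)
}

#' Mean heart rate (bpm)
#'
#' Default convention is the mean of instantaneous rates `60 / RR_i` over
#' accepted intervals; this always dominates `60 / rr_mean` (Jensen), which
#' matches the observed excess of tabulated HR over `60 / RRmean`. The
#' alternative convention is available via `convention = "harmonic"`.
#'
#' @param rr an `rr_series`.
#' @param convention `"instantaneous"` (default) or `"harmonic"`.
#' @return mean HR in bpm, or `NA` when empty.
#' @export
mean_hr <- function(rr, convention = c("instantaneous", "harmonic")) {
  convention <- match.arg(convention)
  x <- accepted(rr)
  if (!length(x)) return(NA_real_)
  if (convention == "instantaneous") mean(60 / x) else 60 / mean(x)
}

#' Root mean square of successive RR differences (s)
#'
#' Differences are taken only between consecutive accepted intervals; a
#' rejected interval breaks the chain.
#'
#' @param rr an `rr_series`.
#' @return RMSSD in seconds, or `NA` with fewer than one usable pair.
#' @export
rmssd <- function(rr) {
  ok <- rr$flag == "ok"
  if (sum(ok) < 2) return(NA_real_)
  idx <- if (!is.null(rr$orig_index)) rr$orig_index else seq_along(rr$intervals_s)
  x <- rr$intervals_s[ok]
  pos <- idx[ok]
  consec <- diff(pos) == 1
  if (!any(consec)) return(NA_real_)
  d <- diff(x)[consec]
  sqrt(mean(d^2))
}

#' Standard deviation of RR intervals (s)
#'
#' Sample standard deviation (divisor n - 1) of accepted intervals, the
#' common HRV-software convention; population divisor available.
#'
#' @param rr an `rr_series`.
#' @param divisor `"n-1"` (default) or `"n"`.
#' @return SDNN in seconds, or `NA` with fewer than 2 accepted intervals.
#' @export
sdnn <- function(rr, divisor = c("n-1", "n")) {
  divisor <- match.arg(divisor)
  x <- accepted(rr)
  if (length(x) < 2) return(NA_real_)
  s <- stats::sd(x)
  if (divisor == "n") s * sqrt((length(x) - 1) / length(x)) else s
}

#' Per-window HRV summaries for one subject
#'
#' One row per analysis window (baseline + 5 phases) with HR, mean RR,
#' RMSSD, SDNN, and the accepted beat count. Windows with fewer than 3
#' beats (2 accepted intervals) yield missing metrics, never zeros.
#'
#' @param rr an `rr_series` covering the recording.
#' @param schedule a [phase_schedule()].
#' @param subject_id subject identifier carried into the output.
#' @return data.frame with columns `subject_id`, `window`, `hr_bpm`,
#'   `rr_mean_s`, `rmssd_s`, `sdnn_s`, `n_beats`.
#' @export
phase_summaries <- function(rr, schedule, subject_id = NA_character_) {
  stopifnot(inherits(schedule, "phase_schedule"))
  rows <- lapply(WINDOW_LABELS, function(lab) {
    w <- schedule_window(schedule, lab)
    wrr <- window_rr(rr, w[1], w[2])
    n_int <- length(wrr$intervals_s)
    if (n_int < 2) {
      data.frame(subject_id = subject_id, window = lab, hr_bpm = NA_real_,
                 rr_mean_s = NA_real_, rmssd_s = NA_real_, sdnn_s = NA_real_,
                 n_beats = if (n_int >= 1) n_int + 1L else 0L,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(subject_id = subject_id, window = lab,
                 hr_bpm = mean_hr(wrr), rr_mean_s = rr_mean(wrr),
                 rmssd_s = rmssd(wrr), sdnn_s = sdnn(wrr),
                 n_beats = n_int + 1L, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Stress reactivity from window summaries
#'
#' The change from baseline to the second stress phase:
#' `delta_hr = HR(stress2) - HR(baseline)` and
#' `delta_rr_mean = RRmean(stress2) - RRmean(baseline)`.
#'
#' @param summaries data.frame from [phase_summaries()] (one subject).
#' @return one-row data.frame with `subject_id`, `delta_hr`,
#'   `delta_rr_mean`; values are `NA` with a `reason` attribute when a
#'   component window is missing.
#' @export
reactivity <- function(summaries) {
  b <- summaries[summaries$window == "baseline", ]
  s2 <- summaries[summaries$window == "stress2", ]
  id <- summaries$subject_id[1]
  if (nrow(b) != 1 || nrow(s2) != 1 || is.na(b$hr_bpm) || is.na(s2$hr_bpm)) {
    out <- data.frame(subject_id = id, delta_hr = NA_real_,
                      delta_rr_mean = NA_real_, stringsAsFactors = FALSE)
    attr(out, "reason") <- "missing baseline or stress2 metrics"
    return(out)
  }
  data.frame(subject_id = id,
             delta_hr = s2$hr_bpm - b$hr_bpm,
             delta_rr_mean = s2$rr_mean_s - b$rr_mean_s,
             stringsAsFactors = FALSE)
}

#' Reactivity table for a whole cohort
#'
#' @param summaries stacked [phase_summaries()] rows for many subjects.
#' @return data.frame with one row per subject.
#' @export
reactivity_table <- function(summaries) {
  ids <- unique(summaries$subject_id)
  do.call(rbind, lapply(ids, function(id)
    reactivity(summaries[summaries$subject_id == id, ])))
}
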