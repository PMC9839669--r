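# Protocol phase schedule: five contiguous four-minute phases of alternating
# relaxation and cognitive stress, preceded by a 30-s baseline window that is
# the opening segment of the first relaxation phase.

PHASE_LABELS <- c("relax1", "stress1", "relax2", "stress2", "relax3")
WINDOW_LABELS <- c("baseline", PHASE_LABELS)

#' Construct a phase schedule
#'
#' A schedule holds the ordered protocol phases and, for each analysis
#' window (baseline plus one per phase), its start and duration. The
#' default analysis window of a phase skips the first `analysis_offset_s`
#' seconds and spans `analysis_dur_s` seconds; the baseline window is the
#' first `baseline_dur_s` seconds of the recording.
#'
#' @param phase_dur_s duration of each phase in seconds.
#' @param baseline_dur_s duration of the baseline window in seconds.
#' @param analysis_offset_s seconds skipped at the start of each phase
#'   before its analysis window opens.
#' @param analysis_dur_s duration of each phase analysis window in seconds.
#' @return an object of class `phase_schedule` with elements `phases`
#'   (data.frame: label, start_s, end_s) and `windows` (data.frame: label,
#'   win_start_s, win_dur_s), plus `total_dur_s`.
#' @export
phase_schedule <- function(phase_dur_s = 240, baseline_dur_s = 30,
                           analysis_offset_s = 20, analysis_dur_s = 180) {
  stopifnot(phase_dur_s > 0, baseline_dur_s > 0,
            analysis_offset_s >= 0, analysis_dur_s > 0,
            analysis_offset_s + analysis_dur_s <= phase_dur_s,
            baseline_dur_s <= phase_dur_s)
  starts <- (seq_along(PHASE_LABELS) - 1) * phase_dur_s
  phases <- data.frame(label = PHASE_LABELS, start_s = starts,
                       end_s = starts + phase_dur_s, stringsAsFactors = FALSE)
  windows <- rbind(
    data.frame(label = "baseline", win_start_s = 0, win_dur_s = baseline_dur_s,
               stringsAsFactors = FALSE),
    data.frame(label = PHASE_LABELS, win_start_s = starts + analysis_offset_s,
               win_dur_s = analysis_dur_s, stringsAsFactors = FALSE))
  out <- list(phases = phases, windows = windows,
              total_dur_s = max(phases$end_s))
  class(out) <- "phase_schedule"
  stopifnot(all(windows$win_start_s + windows$win_dur_s <= out$total_dur_s))
  out
}

#' Default 20-minute stress-relaxation schedule
#'
#' Five contiguous 240-s phases (relax1, stress1, relax2, stress2, relax3),
#' a 30-s baseline window at the start of the recording, and per-phase
#' analysis windows covering \[phase start + 20 s, phase start + 200 s).
#'
#' @return a `phase_schedule`.
#' @export
#' @examples
#' sched <- build_default_schedule()
#' sched$total_dur_s  # 1200 s = 20 min
build_default_schedule <- function() phase_schedule()

#' @export
print.phase_schedule <- function(x, ...) {
  cat("Phase schedule:", x$total_dur_s, "s total\n")
  print(x$phases, row.names = FALSE)
  cat("Analysis windows:\n")
  print(x$windows, row.names = FALSE)
  invisible(x)
}

# Look up one analysis window; returns c(start, dur).
schedule_window <- function(schedule, label) {
  w <- schedule$windows[schedule$windows$label == label, ]
  if (nrow(w) != 1) stop("unknown window label: ", label)
  c(w$win_start_s, w$win_dur_s)
}
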