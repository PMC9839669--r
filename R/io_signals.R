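# Signal and table I/O: two-column delimited text (time_s, mv), a minimal
# single-purpose EDF reader/writer (European Data Format, the clinical
# physiology standard; 16-bit samples), and delimited tables for RR series,
# subjects, and HRV summaries. No installed package provides EDF I/O, so a
# minimal implementation is included here.

#' Write a waveform to disk
#'
#' @param wave a `waveform`.
#' @param path output path.
#' @param format `"delimited"` (two tab-separated columns `time_s`, `mv`)
#'   or `"edf"` (16-bit EDF, one data record per second).
#' @return `path`, invisibly.
#' @export
write_signal <- function(wave, path, format = c("delimited", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(wave, "waveform"))
  if (format == "delimited") {
    t <- wave$start_time_s + (seq_along(wave$samples) - 1) / wave$fs
    utils::write.table(data.frame(time_s = sprintf("%.6f", t),
                                  mv = wave$samples),
                       path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    write_edf(wave, path)
  }
  invisible(path)
}

#' Read a waveform from disk
#'
#' Delimited files must have a uniform time column (relative spacing
#' tolerance 1e-6); the sampling rate is inferred from it. EDF files are
#' read with the bundled minimal reader (first channel by default).
#'
#' @param path input path.
#' @param format `"delimited"`, `"edf"`, or `"auto"` (by extension).
#' @param channel channel index for EDF files.
#' @return a `waveform`.
#' @export
read_signal <- function(path, format = c("auto", "delimited", "edf"),
                        channel = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited"
  if (format == "edf") return(read_edf(path, channel))
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("time_s", "mv") %in% names(d)))
    stop("delimited signal needs columns time_s and mv")
  dt <- diff(d$time_s)
  if (length(dt) < 1 || any(dt <= 0)) stop("time column must be increasing")
  if ((max(dt) - min(dt)) / mean(dt) > 1e-4)
    stop("non-uniform sampling in delimited signal")
  waveform(d$mv, fs = 1 / mean(dt), start_time_s = d$time_s[1])
}

# --- minimal EDF (one or more channels, identical fs, 1-s records) -------

pad <- function(x, n) {
  s <- substr(as.character(x), 1, n)
  formatC(s, width = n, flag = "-")
}

write_edf <- function(wave, path) {
  fs <- wave$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires integer fs")
  fs <- as.integer(round(fs))
  x <- wave$samples
  n_rec <- ceiling(length(x) / fs)
  x <- c(x, rep(0, n_rec * fs - length(x)))
  num8 <- function(v) {   # shortest representation fitting the 8-char field
    for (d in 6:1) {
      s <- formatC(v, format = "g", digits = d)
      if (nchar(s) <= 8) return(s)
    }
    formatC(v, format = "e", digits = 0)
  }
  pmin_s <- num8(min(x)); pmax_s <- num8(max(x))
  pmin_ <- as.numeric(pmin_s); pmax_ <- as.numeric(pmax_s)
  if (pmax_ <= pmin_) { pmax_ <- pmin_ + 1; pmax_s <- num8(pmax_) }
  x <- pmin(pmax(x, pmin_), pmax_)
  dmin <- -32768L; dmax <- 32767L
  dig <- as.integer(round((x - pmin_) / (pmax_ - pmin_) *
                            (dmax - dmin) + dmin))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("synthetic subject", 80), pad("synthetic recording", 80),
    pad("01.01.20", 8), pad("00.00.00", 8), pad(256 + 256, 8), pad("", 44),
    pad(n_rec, 8), pad(1, 8), pad(1, 4))
  writeChar(hdr, con, eos = NULL)
  ch <- paste0(pad(wave$channel_label, 16), pad("synthetic", 80), pad("mV", 8),
               pad(pmin_s, 8), pad(pmax_s, 8),
               pad(dmin, 8), pad(dmax, 8), pad("", 80), pad(fs, 8), pad("", 32))
  writeChar(ch, con, eos = NULL)
  writeBin(dig, con, size = 2, endian = "little")
  invisible(path)
}

read_edf <- function(path, channel = 1L) {
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 8)                       # version
  readChar(con, 160)                     # patient + recording ids
  readChar(con, 16)                      # date + time
  readChar(con, 8)                       # header bytes
  readChar(con, 44)                      # reserved
  n_rec <- as.integer(readChar(con, 8))
  rec_dur <- as.numeric(readChar(con, 8))
  ns <- as.integer(readChar(con, 4))
  if (channel > ns) stop("EDF file has only ", ns, " channel(s)")
  labels <- trimws(vapply(seq_len(ns), function(i) readChar(con, 16), ""))
  vapply(seq_len(ns), function(i) readChar(con, 80), "")   # transducer
  vapply(seq_len(ns), function(i) readChar(con, 8), "")    # unit
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) readChar(con, 8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) readChar(con, 8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) readChar(con, 8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) readChar(con, 8), ""))
  vapply(seq_len(ns), function(i) readChar(con, 80), "")   # prefilter
  nsamp <- as.integer(vapply(seq_len(ns), function(i) readChar(con, 8), ""))
  vapply(seq_len(ns), function(i) readChar(con, 32), "")   # reserved
  out <- numeric(0)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      vals <- readBin(con, integer(), n = nsamp[s], size = 2,
                      endian = "little", signed = TRUE)
      if (s == channel) out <- c(out, vals)
    }
  }
  g <- (pmax_[channel] - pmin_[channel]) / (dmax[channel] - dmin[channel])
  phys <- (out - dmin[channel]) * g + pmin_[channel]
  waveform(phys, fs = nsamp[channel] / rec_dur,
           channel_label = labels[channel])
}

# --- delimited tables ----------------------------------------------------

#' Write an RR series as delimited text
#' @param rr an `rr_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rr <- function(rr, path) {
  utils::write.table(data.frame(rr_s = rr$intervals_s,
                                end_time_s = rr$end_times_s,
                                flag = rr$flag),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an RR series from delimited text
#' @param path input path.
#' @return an `rr_series`.
#' @export
read_rr <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  structure(list(intervals_s = d$rr_s, end_times_s = d$end_time_s,
                 flag = d$flag,
                 beat_times_s = c(d$end_time_s[1] - d$rr_s[1], d$end_time_s)),
            class = "rr_series")
}

#' Write and read delimited tables (tab-separated, header row)
#' @param x a data.frame.
#' @param path file path.
#' @return `path` (write) or a data.frame (read).
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write or read a simulation/extraction configuration as YAML
#' @param cfg a config list.
#' @param path file path.
#' @return `path` (write) or a config list (read).
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @param class_name S3 class to restore on read.
#' @export
read_config <- function(path, class_name = "sim_config") {
  cfg <- yaml::read_yaml(path)
  # yaml loses named-vector names on some nested fields; restore defaults' shape
  defaults <- if (class_name == "sim_config") default_sim_config() else extract_config()
  for (nm in names(defaults)) {
    if (!is.null(cfg[[nm]]) && !is.null(names(defaults[[nm]])) &&
        is.null(names(cfg[[nm]])) && is.atomic(defaults[[nm]]) &&
        length(cfg[[nm]]) == length(defaults[[nm]]))
      names(cfg[[nm]]) <- names(defaults[[nm]])
  }
  out <- defaults
  for (nm in names(cfg)) out[[nm]] <- cfg[[nm]]
  class(out) <- class_name
  out
}
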