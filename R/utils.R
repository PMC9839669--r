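# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's `.Random.seed`, so seeded operations do
#' not perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive per-subject, per-stage seeds from a master seed
#'
#' One integer seed per subject and simulation stage, drawn without
#' replacement from the master stream so that each subject's recording is
#' reproducible in isolation.
#'
#' @param master_seed integer master seed.
#' @param n number of subjects.
#' @param stages character vector of stage names.
#' @return integer matrix `n x length(stages)` with stage names as columns.
#' @export
derive_seeds <- function(master_seed, n, stages = c("subject", "rr", "contaminate", "nrs")) {
  stopifnot(n >= 1)
  with_seed(master_seed, {
    m <- matrix(sample.int(.Machine$integer.max - 1L, n * length(stages)),
                nrow = n, ncol = length(stages))
    colnames(m) <- stages
    m
  })
}

# Two-sided band power of a real signal from its discrete Fourier transform,
# summed over [lo, hi) Hz. Used for SNR scaling and spectral checks.
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n^2
  f <- (seq_len(n) - 1) * fs / n
  sel <- f >= lo & f < hi & f <= fs / 2
  2 * sum(p[sel])
}

# Simple raw periodogram on a uniform frequency grid (one-sided).
periodogram_est <- function(wave) {
  stopifnot(inherits(wave, "waveform"))
  x <- wave$samples
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n^2
  nyq <- floor(n / 2)
  f <- (seq_len(nyq + 1) - 1) * wave$fs / n
  pow <- p[seq_len(nyq + 1)] * 2
  pow[1] <- p[1]
  structure(list(frequencies = f, power = pow), class = "spectral_estimate")
}

fmt3 <- function(x) signif(x, 3)
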