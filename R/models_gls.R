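# Baseline-adjusted reactivity models: long-format outcome tables and
# feasible generalized least squares with an exchangeable (compound
# symmetric) within-subject correlation, the minimal structure justifying
# GLS over ordinary least squares for repeated protocol phases.

TIME_LEVELS <- c("relax1", "stress1", "relax2", "stress2", "relax3")

#' Build the long-format modelling table for one outcome
#'
#' One row per subject and phase (relax1 is the reference level), with the
#' subject's baseline value of the same metric as a covariate plus BMI,
#' smoking and physical activity. Subjects without a valid baseline are
#' excluded with a warning; phases with missing outcome values are dropped
#' listwise (with a log message), mirroring how incomplete recordings
#' reduce the observation count.
#'
#' @param summaries stacked [phase_summaries()] rows.
#' @param subjects cohort subject table (needs `subject_id`, `group` or
#'   `cluster`, `bmi`, `smoker`, `physically_active`).
#' @param outcome one of `"hr_bpm"`, `"rr_mean_s"`, `"rmssd_s"`,
#'   `"sdnn_s"` (aliases `"HR"`, `"RRmean"`, `"RMSSD"`, `"SDNN"`).
#' @param group_col column of `subjects` used as the grouping factor
#'   (default `"group"`; use `"cluster"` for within-FM models).
#' @return data.frame with `subject_id`, `group`, `time`, `y`, `baseline`,
#'   `bmi`, `smoker`, `physically_active`.
#' @export
build_long_table <- function(summaries, subjects, outcome = "hr_bpm",
                             group_col = "group") {
  alias <- c(HR = "hr_bpm", RRmean = "rr_mean_s", RMSSD = "rmssd_s",
             SDNN = "sdnn_s")
  if (outcome %in% names(alias)) outcome <- alias[[outcome]]
  stopifnot(outcome %in% c("hr_bpm", "rr_mean_s", "rmssd_s", "sdnn_s"),
            group_col %in% names(subjects))
  rows <- list()
  dropped_base <- character(0); dropped_phase <- 0L
  for (id in unique(summaries$subject_id)) {
    s <- summaries[summaries$subject_id == id, ]
    base <- s[s$window == "baseline", outcome]
    if (length(base) != 1 || is.na(base)) {
      dropped_base <- c(dropped_base, id)
      next
    }
    subj <- subjects[subjects$subject_id == id, ]
    if (nrow(subj) != 1) next
    ph <- s[s$window %in% TIME_LEVELS, ]
    ok <- !is.na(ph[[outcome]])
    dropped_phase <- dropped_phase + sum(!ok)
    ph <- ph[ok, ]
    if (!nrow(ph)) next
    rows[[id]] <- data.frame(
      subject_id = id,
      group = subj[[group_col]],
      time = factor(ph$window, levels = TIME_LEVELS),
      y = ph[[outcome]],
      baseline = base,
      bmi = subj$bmi, smoker = subj$smoker,
      physically_active = subj$physically_active,
      stringsAsFactors = FALSE)
  }
  if (length(dropped_base))
    warning("excluded (missing baseline): ", paste(dropped_base, collapse = ", "))
  if (dropped_phase > 0)
    message(dropped_phase, " phase rows dropped for missing outcome values")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (is.character(out$group)) {
    lev <- if (all(out$group %in% c("FM", "control")))
      c("control", "FM") else sort(unique(out$group))
    out$group <- factor(out$group, levels = lev)
  }
  out
}

#' Feasible generalized least squares with exchangeable correlation
#'
#' Iterates between (1) (generalized) least squares for the coefficients
#' and (2) a moment estimate of the common within-subject correlation
#' `rho` from residual cross-products, until `rho` converges. Confidence
#' intervals and p-values use a t reference with residual degrees of
#' freedom. With `rho` fixed at 0 the fit is ordinary least squares.
#'
#' @param formula model formula, e.g. `y ~ group * time + baseline`.
#' @param data long-format data.frame (one row per subject-phase).
#' @param subject_col name of the subject-id column grouping repeated rows.
#' @param rho `NULL` to estimate (default) or a fixed value.
#' @param tol convergence tolerance on `rho`.
#' @param max_iter maximum iterations.
#' @param conf_level confidence level for Wald intervals.
#' @return an object of class `hrv_gls`: `coefficients` (data.frame with
#'   estimate, CI bounds, t, p), `rho`, `sigma2`, `n`, `df_residual`,
#'   `converged`, `iterations`, `formula`.
#' @export
fit_gls <- function(formula, data, subject_col = "subject_id", rho = NULL,
                    tol = 1e-6, max_iter = 50, conf_level = 0.95) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  X <- stats::model.matrix(formula, mf)
  y <- stats::model.response(mf)
  omit <- attr(mf, "na.action")
  keep <- if (is.null(omit)) seq_len(nrow(data)) else setdiff(seq_len(nrow(data)), omit)
  subj <- data[[subject_col]][keep]
  n <- length(y); p <- ncol(X)
  if (qr(X)$rank < p) {
    cf <- stats::lm.fit(X, y)$coefficients
    stop("rank-deficient design; aliased columns: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  groups <- split(seq_len(n), subj)
  m_max <- max(lengths(groups))
  rho_fixed <- !is.null(rho)
  rho_cur <- if (rho_fixed) rho else 0
  est_rho <- function(e, s2) {
    num <- 0; pairs <- 0
    for (g in groups) {
      m <- length(g)
      if (m < 2) next
      eg <- e[g]
      num <- num + (sum(eg)^2 - sum(eg^2)) / 2
      pairs <- pairs + m * (m - 1) / 2
    }
    if (pairs == 0) return(0)
    r <- num / (pairs * s2)
    min(max(r, -1 / (m_max - 1) + 1e-6), 0.999)
  }
  whiten <- function(v, rho_w) {
    # compound-symmetry whitening: subtract a fraction of the group mean,
    # then scale; transformed OLS equals GLS
    out <- numeric(length(v))
    for (g in groups) {
      m <- length(g)
      cfac <- 1 - sqrt((1 - rho_w) / (1 - rho_w + m * rho_w))
      out[g] <- (v[g] - cfac * mean(v[g])) / sqrt(1 - rho_w)
    }
    out
  }
  beta <- NULL; s2 <- NULL; XtXi <- NULL
  iter <- 0; converged <- FALSE
  repeat {
    iter <- iter + 1
    if (abs(rho_cur) < 1e-12) {
      Xw <- X; yw <- y
    } else {
      Xw <- apply(X, 2, whiten, rho_w = rho_cur)
      yw <- whiten(y, rho_cur)
    }
    fit <- stats::lm.fit(Xw, yw)
    beta <- fit$coefficients
    s2 <- sum(fit$residuals^2) / (n - p)
    XtXi <- chol2inv(chol(crossprod(Xw)))
    if (rho_fixed) { converged <- TRUE; break }
    e_raw <- y - as.numeric(X %*% beta)
    s2_raw <- sum(e_raw^2) / (n - p)
    rho_new <- est_rho(e_raw, s2_raw)
    if (abs(rho_new - rho_cur) < tol) { rho_cur <- rho_new; converged <- TRUE; break }
    rho_cur <- rho_new
    if (iter >= max_iter) break
  }
  se <- sqrt(s2 * diag(XtXi))
  tval <- beta / se
  dfres <- n - p
  alpha <- 1 - conf_level
  ci <- qt(1 - alpha / 2, dfres) * se
  coefs <- data.frame(term = colnames(X), estimate = as.numeric(beta),
                      se = se, ci_low = beta - ci, ci_high = beta + ci,
                      t = tval, p = 2 * stats::pt(-abs(tval), dfres),
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  structure(list(coefficients = coefs, rho = rho_cur, sigma2 = s2, n = n,
                 df_residual = dfres, converged = converged,
                 iterations = iter, formula = formula, vcov = s2 * XtXi),
            class = "hrv_gls")
}

#' @export
print.hrv_gls <- function(x, ...) {
  cat("Feasible GLS (exchangeable within-subject correlation)\n")
  cat(sprintf("n = %d, rho = %.4f, sigma2 = %.5g, converged: %s (%d iter)\n",
              x$n, x$rho, x$sigma2, x$converged, x$iterations))
  out <- x$coefficients
  out[, -1] <- lapply(out[, -1], function(v) signif(v, 4))
  print(out, row.names = FALSE)
  invisible(x)
}

#' Fit the reactivity model for one outcome
#'
#' Convenience wrapper building the long table and fitting
#' `y ~ group * time + baseline`, optionally adjusted for BMI, smoking
#' and physical activity.
#'
#' @param summaries stacked [phase_summaries()] rows.
#' @param subjects cohort subject table.
#' @param outcome outcome name (see [build_long_table()]).
#' @param adjusted include lifestyle covariates if `TRUE`.
#' @param group_col grouping column (default `"group"`).
#' @return an `hrv_gls` fit with the long table attached as `$data`.
#' @export
fit_reactivity_model <- function(summaries, subjects, outcome = "hr_bpm",
                                 adjusted = FALSE, group_col = "group") {
  rows <- build_long_table(summaries, subjects, outcome, group_col)
  dropped <- character(0)
  if (adjusted) {
    cc <- stats::complete.cases(rows[, c("bmi", "smoker", "physically_active")])
    rows <- rows[cc, ]
    # covariates constant in the analysed subset would alias the intercept
    covs <- c("bmi", "smoker", "physically_active")
    dropped <- covs[vapply(covs, function(v) length(unique(rows[[v]])) < 2,
                           logical(1))]
    if (length(dropped))
      message("constant covariate(s) dropped: ", paste(dropped, collapse = ", "))
  }
  f <- if (adjusted)
    stats::reformulate(c("group * time", "baseline",
                         setdiff(c("bmi", "smoker", "physically_active"),
                                 dropped)),
                       response = "y")
  else
    y ~ group * time + baseline
  fit <- fit_gls(f, rows)
  fit$data <- rows
  fit$dropped_covariates <- dropped
  fit
}
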