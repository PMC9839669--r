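# Group-comparison utilities: two-group tests for baseline characteristics
# and one-way ANOVA with Tukey HSD post-hoc testing for cluster contrasts.

#' Two-group baseline comparisons
#'
#' For each HRV metric and analysis window, both the Student's t-test and
#' the Mann-Whitney U-test are reported (the two conventions used for
#' continuous variables). Categorical covariates (smoking, physical
#' activity) are compared with the chi-squared test with Yates continuity
#' correction on the 2x2 table.
#'
#' @param subjects cohort subject table with `group`.
#' @param summaries stacked [phase_summaries()] rows.
#' @return data.frame with columns `variable`, `window`, `method`,
#'   `statistic`, `p`, `mean_fm`, `mean_control`, `flag`.
#' @export
baseline_comparisons <- function(subjects, summaries) {
  stopifnot(all(c("FM", "control") %in% subjects$group))
  metrics <- c("hr_bpm", "rr_mean_s", "rmssd_s", "sdnn_s")
  rows <- list()
  merged <- merge(summaries, subjects[, c("subject_id", "group")],
                  by = "subject_id")
  for (m in metrics) for (w in WINDOW_LABELS) {
    d <- merged[merged$window == w, ]
    x <- d[[m]][d$group == "FM"]; y <- d[[m]][d$group == "control"]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) next
    flag <- ""
    if (stats::sd(c(x, y)) == 0) {
      tt <- list(statistic = 0, p.value = 1); flag <- "zero variance"
      wt <- list(statistic = NA, p.value = 1)
    } else {
      tt <- stats::t.test(x, y, var.equal = TRUE)
      wt <- stats::wilcox.test(x, y, exact = FALSE)
    }
    rows[[length(rows) + 1]] <- data.frame(
      variable = m, window = w, method = "student_t",
      statistic = unname(tt$statistic), p = tt$p.value,
      mean_fm = mean(x), mean_control = mean(y), flag = flag,
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      variable = m, window = w, method = "mann_whitney",
      statistic = unname(wt$statistic), p = wt$p.value,
      mean_fm = mean(x), mean_control = mean(y), flag = flag,
      stringsAsFactors = FALSE)
  }
  for (v in c("smoker", "physically_active")) {
    if (!v %in% names(subjects)) next
    tab <- table(subjects$group == "FM", subjects[[v]])
    if (!all(dim(tab) == c(2, 2))) next
    ct <- stats::chisq.test(tab, correct = TRUE)
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, window = NA_character_, method = "chi_square_yates",
      statistic = unname(ct$statistic), p = ct$p.value,
      mean_fm = mean(subjects[[v]][subjects$group == "FM"]),
      mean_control = mean(subjects[[v]][subjects$group == "control"]),
      flag = "", stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Yates-corrected chi-squared test from 2x2 counts
#'
#' Convenience wrapper: `counts` are given as (group1 yes, group1 no,
#' group2 yes, group2 no).
#'
#' @param a,b,c,d the four cell counts, row-wise.
#' @return the `htest` object from [stats::chisq.test()].
#' @export
chisq_yates_2x2 <- function(a, b, c, d) {
  stats::chisq.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE),
                    correct = TRUE)
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Groups with fewer than 2 observations are excluded with a warning.
#' Family-wise adjusted p-values come from the studentized-range
#' distribution; with two groups the Tukey p equals the pooled-variance
#' t-test p.
#'
#' @param values numeric outcome vector.
#' @param group_labels grouping vector of the same length.
#' @return list with `anova` (one-row data.frame: F, df, p) and `tukey`
#'   (data.frame of pairwise contrasts: pair, diff, ci_low, ci_high,
#'   p_adj).
#' @export
anova_tukey <- function(values, group_labels) {
  ok <- !is.na(values) & !is.na(group_labels)
  values <- values[ok]; g <- factor(group_labels[ok])
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding groups with < 2 observations: ",
            paste(small, collapse = ", "))
    keep <- !(g %in% small)
    values <- values[keep]; g <- droplevels(g[keep])
  }
  if (nlevels(g) < 2) stop("need at least 2 groups with 2+ observations")
  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  out_tk <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                       ci_low = tk[, "lwr"], ci_high = tk[, "upr"],
                       p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  rownames(out_tk) <- NULL
  list(anova = data.frame(F = an$`F value`[1], df1 = an$Df[1], df2 = an$Df[2],
                          p = an$`Pr(>F)`[1]),
       tukey = out_tk)
}
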