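# Constrained k-means stratification of FM patients on z-transformed
# stress-reactivity variables, with feasibility enumeration under the
# n >= 10 * d * k sample-size rule, minimum within-cluster sum of squares
# model selection, and cluster characterisation.

#' z-transform a numeric vector
#'
#' `(x - mean) / sd` with the sample standard deviation (divisor n - 1).
#'
#' @param values numeric vector, at least 2 values with non-zero variance.
#' @return z-scores with mean 0 and sd 1.
#' @export
z_transform <- function(values) {
  stopifnot(length(values) >= 2)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("zero variance: cannot z-transform")
  (values - mean(values)) / s
}

#' Enumerate feasible clustering configurations
#'
#' Under the sample-size rule `n >= 10 * d * k` (d clustering variables,
#' k clusters). Mode `"published"` returns the feasible set as applied in
#' the original 51-patient study: both variables with k = 2, and each
#' single variable with k = 2 or 3 (the rule as reported stops at k = 3
#' for single variables). Mode `"rule"` enumerates every variable subset
#' and k up to `max_k` satisfying the inequality literally.
#'
#' @param n number of patients.
#' @param candidate_vars character vector of candidate variable names.
#' @param max_k largest k considered in `"rule"` mode.
#' @param mode `"published"` or `"rule"`.
#' @return list of configs, each `list(vars, d, k)`.
#' @export
enumerate_feasible_configs <- function(n,
                                       candidate_vars = c("delta_hr", "delta_rr_mean"),
                                       max_k = 5, mode = c("published", "rule")) {
  mode <- match.arg(mode)
  stopifnot(n >= 20, length(candidate_vars) >= 1)
  cfgs <- list()
  add <- function(vars, k) {
    if (n >= 10 * length(vars) * k)
      cfgs[[length(cfgs) + 1]] <<- list(vars = vars, d = length(vars), k = k)
  }
  if (mode == "published") {
    if (length(candidate_vars) >= 2) add(candidate_vars[1:2], 2)
    for (v in candidate_vars) { add(v, 2); add(v, 3) }
  } else {
    subsets <- unlist(lapply(seq_along(candidate_vars), function(d)
      utils::combn(candidate_vars, d, simplify = FALSE)), recursive = FALSE)
    for (vars in subsets) for (k in 2:max_k) add(vars, k)
  }
  cfgs
}

# k-means++ initial centres for one restart (uses the current RNG stream).
kmeanspp_init <- function(pts, k) {
  n <- nrow(pts)
  centers <- matrix(NA_real_, k, ncol(pts))
  centers[1, ] <- pts[sample.int(n, 1), ]
  d2 <- rowSums((pts - matrix(centers[1, ], n, ncol(pts), byrow = TRUE))^2)
  for (j in 2:k) {
    if (all(d2 == 0)) {
      centers[j, ] <- pts[sample.int(n, 1), ]
    } else {
      centers[j, ] <- pts[sample.int(n, 1, prob = d2), ]
    }
    d2 <- pmin(d2, rowSums((pts - matrix(centers[j, ], n, ncol(pts),
                                         byrow = TRUE))^2))
  }
  centers
}

# One Lloyd run to a fixed point; empty clusters are reseeded with the
# point farthest from its assigned centre.
lloyd <- function(pts, centers, max_iter = 100) {
  n <- nrow(pts); k <- nrow(centers)
  assign_old <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    d2 <- sapply(seq_len(k), function(j)
      rowSums((pts - matrix(centers[j, ], n, ncol(pts), byrow = TRUE))^2))
    if (is.null(dim(d2))) d2 <- matrix(d2, nrow = n)
    assign_new <- max.col(-d2, ties.method = "first")
    for (j in seq_len(k)) {
      if (!any(assign_new == j)) {  # empty-cluster repair
        far <- which.max(d2[cbind(seq_len(n), assign_new)])
        centers[j, ] <- pts[far, ]
        assign_new[far] <- j
      }
    }
    for (j in seq_len(k))
      centers[j, ] <- colMeans(pts[assign_new == j, , drop = FALSE])
    if (all(assign_new == assign_old)) break
    assign_old <- assign_new
  }
  d2 <- sapply(seq_len(k), function(j)
    rowSums((pts - matrix(centers[j, ], n, ncol(pts), byrow = TRUE))^2))
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = n)
  wss <- sum(d2[cbind(seq_len(n), assign_old)])
  list(assignments = assign_old, centers = centers, wss = wss)
}

#' k-means clustering with k-means++ restarts
#'
#' Lloyd's algorithm from `n_init` k-means++ initialisations, keeping the
#' minimum within-cluster-sum-of-squares (WSS) solution. Deterministic
#' given `seed`; empty clusters during iteration are repaired by reseeding
#' the farthest point.
#'
#' @param points numeric matrix (rows = observations) or vector.
#' @param k number of clusters (at most the number of distinct points).
#' @param seed integer seed.
#' @param n_init number of restarts.
#' @return an object of class `hrv_kmeans`: `assignments`, `centers`,
#'   `wss`, `sizes`, `k`, `n_init`, `seed`.
#' @export
kmeans_reactivity <- function(points, k, seed = 1L, n_init = 100) {
  pts <- if (is.null(dim(points))) matrix(as.numeric(points), ncol = 1)
         else as.matrix(points)
  stopifnot(k >= 1, n_init >= 1)
  n_distinct <- nrow(unique(pts))
  if (k > n_distinct) stop("k exceeds the number of distinct points")
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_init)) {
      res <- lloyd(pts, kmeanspp_init(pts, k))
      if (is.null(best) || res$wss < best$wss - 1e-12) best <- res
    }
  })
  structure(list(assignments = best$assignments, centers = best$centers,
                 wss = best$wss, sizes = as.integer(table(factor(best$assignments,
                                                                 levels = seq_len(k)))),
                 k = k, n_init = n_init, seed = seed),
            class = "hrv_kmeans")
}

#' Run all feasible clusterings on a reactivity table
#'
#' z-transforms each clustering variable, runs [kmeans_reactivity()] for
#' every feasible configuration, and records the configuration with each
#' result.
#'
#' @param reactivity data.frame from [reactivity_table()] (complete cases
#'   are required and enforced).
#' @param configs list from [enumerate_feasible_configs()]; `NULL`
#'   enumerates in `"published"` mode from the available variables.
#' @param seed integer seed.
#' @param n_init restarts per configuration.
#' @return list of `hrv_kmeans` objects, each with `$config` attached.
#' @export
run_feasible_clusterings <- function(reactivity, configs = NULL, seed = 1L,
                                     n_init = 100) {
  vars <- intersect(c("delta_rr_mean", "delta_hr"), names(reactivity))
  cc <- stats::complete.cases(reactivity[, vars, drop = FALSE])
  react <- reactivity[cc, ]
  if (is.null(configs))
    configs <- enumerate_feasible_configs(nrow(react), vars, mode = "published")
  lapply(seq_along(configs), function(i) {
    cf <- configs[[i]]
    z <- sapply(cf$vars, function(v) z_transform(react[[v]]))
    res <- kmeans_reactivity(z, cf$k, seed = seed + i, n_init = n_init)
    res$config <- cf
    res$subject_id <- react$subject_id
    res
  })
}

#' Select the minimum-WSS clustering
#'
#' Returns the candidate with the smallest total within-cluster sum of
#' squares (computed on z-scored variables so configurations of different
#' dimension are compared on a common scale); ties are broken by fewer
#' variables, then fewer clusters.
#'
#' @param results list of `hrv_kmeans` results from
#'   [run_feasible_clusterings()].
#' @return the selected `hrv_kmeans`.
#' @export
select_clustering <- function(results) {
  stopifnot(length(results) >= 1)
  ord <- order(sapply(results, `[[`, "wss"),
               sapply(results, function(r) r$config$d),
               sapply(results, function(r) r$config$k))
  results[[ord[1]]]
}

#' Relabel clusters by ascending baseline heart rate
#'
#' Makes reports invariant to k-means label permutation: cluster 1 becomes
#' the cluster with the lowest mean baseline HR.
#'
#' @param result an `hrv_kmeans` with `$subject_id`.
#' @param summaries stacked [phase_summaries()] rows (for baseline HR).
#' @return the result with relabelled `assignments`, `sizes`, `centers`.
#' @export
relabel_by_baseline_hr <- function(result, summaries) {
  base <- summaries[summaries$window == "baseline",
                    c("subject_id", "hr_bpm")]
  hr <- base$hr_bpm[match(result$subject_id, base$subject_id)]
  means <- tapply(hr, result$assignments, mean, na.rm = TRUE)
  ord <- order(means)             # old label -> rank position
  newlab <- match(result$assignments, as.integer(names(means))[ord])
  result$assignments <- newlab
  result$sizes <- as.integer(table(factor(newlab, levels = seq_len(result$k))))
  result$centers <- result$centers[as.integer(names(means))[ord], , drop = FALSE]
  result
}

#' @export
print.hrv_kmeans <- function(x, ...) {
  cat(sprintf("k-means: k = %d, WSS = %.4f, sizes = %s\n",
              x$k, x$wss, paste(x$sizes, collapse = "/")))
  if (!is.null(x$config))
    cat("variables:", paste(x$config$vars, collapse = ", "), "\n")
  invisible(x)
}

#' Characterise clusters by questionnaires and trajectories
#'
#' Compares questionnaire variables across clusters with one-way ANOVA and
#' Tukey HSD; questionnaire items with missingness above
#' `missing_threshold` are excluded (with a log entry in the output).
#' HRV and NRS pain/stress trajectories are refit with the sparse GLS
#' model `value ~ cluster * time + baseline` (cluster 1, the lowest
#' baseline-HR cluster, is the reference).
#'
#' @param subjects cohort subject table (FM rows are used).
#' @param result a relabelled `hrv_kmeans` with `$subject_id`.
#' @param summaries stacked [phase_summaries()] rows.
#' @param nrs long NRS table (columns `subject_id`, `timepoint`,
#'   `nrs_pain`, `nrs_stress`), optional.
#' @param missing_threshold exclusion threshold on item missingness.
#' @return list with `questionnaires` (per-variable ANOVA + Tukey),
#'   `excluded_items`, `gls` (per-outcome `hrv_gls` fits), `sizes`.
#' @export
characterize_clusters <- function(subjects, result, summaries, nrs = NULL,
                                  missing_threshold = 0.2) {
  stopifnot(inherits(result, "hrv_kmeans"), !is.null(result$subject_id))
  fm <- subjects[match(result$subject_id, subjects$subject_id), ]
  if (any(result$sizes == 0)) stop("empty cluster in characterisation")
  fm$cluster <- factor(result$assignments)
  qvars <- c("fiq_total", paste0("fiq_item", c(1, 2, 3, 4, 5:10)),
             "pcs", "pss", "stai_a", "stai_b")
  qvars <- intersect(qvars, names(fm))
  missing_frac <- sapply(qvars, function(v) mean(is.na(fm[[v]])))
  excluded <- qvars[missing_frac > missing_threshold]
  tested <- setdiff(qvars, excluded)
  qres <- lapply(tested, function(v) anova_tukey(fm[[v]], fm$cluster))
  names(qres) <- tested

  cluster_tab <- data.frame(subject_id = result$subject_id,
                            cluster = paste0("c", result$assignments),
                            stringsAsFactors = FALSE)
  subj_cl <- merge(subjects, cluster_tab, by = "subject_id")
  gls_fits <- list()
  for (oc in c("hr_bpm", "rr_mean_s", "rmssd_s", "sdnn_s")) {
    fit <- tryCatch(
      fit_reactivity_model(summaries[summaries$subject_id %in%
                                       cluster_tab$subject_id, ],
                           subj_cl, oc, adjusted = FALSE,
                           group_col = "cluster"),
      error = function(e) NULL)
    gls_fits[[oc]] <- fit
  }
  if (!is.null(nrs)) {
    for (oc in c("nrs_pain", "nrs_stress")) {
      long <- nrs_long_table(nrs, subj_cl, oc)
      if (!is.null(long) && nrow(long) > 0)
        gls_fits[[oc]] <- tryCatch(
          fit_gls(y ~ group * time + baseline, long), error = function(e) NULL)
    }
  }
  list(questionnaires = qres, excluded_items = excluded, gls = gls_fits,
       sizes = result$sizes)
}

# NRS ratings in the same long shape as the HRV models: timepoint 1 is the
# baseline covariate; timepoints 2-6 map to the five phases.
nrs_long_table <- function(nrs, subjects, outcome = "nrs_stress") {
  stopifnot(outcome %in% names(nrs))
  rows <- list()
  for (id in unique(nrs$subject_id)) {
    d <- nrs[nrs$subject_id == id, ]
    d <- d[order(d$timepoint), ]
    subj <- subjects[subjects$subject_id == id, ]
    if (nrow(subj) != 1 || nrow(d) != 6) next
    rows[[id]] <- data.frame(
      subject_id = id,
      group = if ("cluster" %in% names(subj)) subj$cluster else subj$group,
      time = factor(TIME_LEVELS, levels = TIME_LEVELS),
      y = d[[outcome]][2:6],
      baseline = d[[outcome]][1],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) {
    rownames(out) <- NULL
    out$group <- factor(out$group)
  }
  out
}
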