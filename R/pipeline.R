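# End-to-end driver: simulate -> extract -> HRV -> models -> clustering ->
# report, with a run manifest recording the configuration, master seed and
# file digests so reruns are verifiably identical.

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates the cohort, recovers RR series from each subject's
#' contaminated recording (or uses the ground-truth RR when
#' `truth_bypass = TRUE`), computes per-window HRV summaries, fits the
#' unadjusted and adjusted group-reactivity GLS models for each outcome,
#' clusters the FM patients on z-transformed reactivity (minimum-WSS
#' selection over the feasible configurations), characterises the
#' clusters, and writes all tables plus a text report and JSON manifest
#' under `out_dir`.
#'
#' @param cfg a [default_sim_config()].
#' @param out_dir output directory (created if needed).
#' @param truth_bypass skip signal extraction and use ground-truth RR.
#' @param cluster run the clustering stage (requires enough FM patients
#'   for at least one feasible configuration).
#' @param extract_cfg an [extract_config()].
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(cfg = default_sim_config(), out_dir,
                         truth_bypass = FALSE, cluster = TRUE,
                         extract_cfg = extract_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    warnings_log <<- c(warnings_log, msg)
    message(msg)
  }
  if (cluster && cfg$n_fm < 20)
    stop("clustering stage infeasible: n_fm = ", cfg$n_fm,
         " < 20 required by the n >= 10 * d * k rule; ",
         "rerun with cluster = FALSE or more FM patients")

  cohort <- generate_cohort(cfg)
  write_table_tsv(cohort$subjects, file.path(out_dir, "subjects.tsv"))
  write_table_tsv(cohort$truth_hrv, file.path(out_dir, "truth_hrv.tsv"))
  write_table_tsv(cohort$nrs, file.path(out_dir, "nrs.tsv"))
  write_config(cfg, file.path(out_dir, "config.yaml"))

  if (truth_bypass) {
    summaries <- cohort$truth_hrv
  } else {
    ids <- cohort$subjects$subject_id
    sm <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      wave <- cohort_waveform(cohort, i)
      res <- extract_rr(wave, extract_cfg)
      sm[[i]] <- phase_summaries(res$rr, cohort$schedule, ids[i])
    }
    summaries <- do.call(rbind, sm)
  }
  write_table_tsv(summaries, file.path(out_dir, "hrv_summaries.tsv"))

  comp <- baseline_comparisons(cohort$subjects, summaries)
  write_table_tsv(comp, file.path(out_dir, "group_comparisons.tsv"))

  outcomes <- c("hr_bpm", "rr_mean_s", "rmssd_s", "sdnn_s")
  fits <- list()
  for (oc in outcomes) {
    for (adj in c(FALSE, TRUE)) {
      key <- paste0(oc, if (adj) "_adjusted" else "_unadjusted")
      fits[[key]] <- fit_reactivity_model(summaries, cohort$subjects, oc, adj)
      write_table_tsv(fits[[key]]$coefficients,
                      file.path(out_dir, paste0("gls_", key, ".tsv")))
    }
  }

  cluster_out <- NULL
  if (cluster) {
    react <- reactivity_table(summaries)
    react <- merge(react,
                   cohort$subjects[cohort$subjects$group == "FM",
                                   c("subject_id", "true_cluster")],
                   by = "subject_id")
    candidates <- run_feasible_clusterings(react, seed = cfg$master_seed)
    chosen <- select_clustering(candidates)
    chosen <- relabel_by_baseline_hr(chosen, summaries)
    note("clustering selected: vars = ",
         paste(chosen$config$vars, collapse = "+"), ", k = ", chosen$config$k,
         ", WSS = ", signif(chosen$wss, 4))
    assign_tab <- data.frame(subject_id = chosen$subject_id,
                             cluster = chosen$assignments)
    write_table_tsv(assign_tab, file.path(out_dir, "cluster_assignments.tsv"))
    wss_tab <- do.call(rbind, lapply(candidates, function(r)
      data.frame(vars = paste(r$config$vars, collapse = "+"),
                 d = r$config$d, k = r$config$k, wss = r$wss)))
    write_table_tsv(wss_tab, file.path(out_dir, "cluster_model_selection.tsv"))
    chr <- characterize_clusters(cohort$subjects, chosen, summaries,
                                 cohort$nrs)
    qtab <- do.call(rbind, lapply(names(chr$questionnaires), function(v)
      data.frame(variable = v, F = chr$questionnaires[[v]]$anova$F,
                 p = chr$questionnaires[[v]]$anova$p)))
    write_table_tsv(qtab, file.path(out_dir, "cluster_questionnaires.tsv"))
    for (oc in names(chr$gls)) {
      if (!is.null(chr$gls[[oc]]))
        write_table_tsv(chr$gls[[oc]]$coefficients,
                        file.path(out_dir, paste0("gls_cluster_", oc, ".tsv")))
    }
    cluster_out <- list(selection = wss_tab, chosen = chosen,
                        characterisation = chr)
  }

  report <- render_report(out_dir)
  manifest <- list(
    package_version = as.character(utils::packageVersion("hrvreact")),
    master_seed = cfg$master_seed,
    n_fm = cfg$n_fm, n_control = cfg$n_control,
    truth_bypass = truth_bypass,
    stages = c("simulate", if (!truth_bypass) "extract", "hrv", "model",
               if (cluster) "cluster", "report"),
    warnings = warnings_log,
    file_digests = as.list(tools::md5sum(sort(list.files(out_dir,
      pattern = "\\.(tsv|txt|yaml)$", full.names = TRUE)))))
  names(manifest$file_digests) <- basename(names(manifest$file_digests))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Render the plain-text summary report
#'
#' Group summary statistics (mean, SD, median, min, max) per metric and
#' window, the GLS coefficient tables, and the cluster characterisation,
#' all formatted to 3 significant figures. Sections whose stage outputs
#' are missing are marked unavailable. Regeneration from the same outputs
#' is idempotent.
#'
#' @param out_dir a [run_pipeline()] output directory.
#' @return the report text (character vector), invisibly; also written to
#'   `report.txt` in `out_dir`.
#' @export
render_report <- function(out_dir) {
  lines <- c("HRV stress-reactivity analysis report",
             "=====================================", "")
  p_subj <- file.path(out_dir, "subjects.tsv")
  p_hrv <- file.path(out_dir, "hrv_summaries.tsv")
  if (file.exists(p_subj) && file.exists(p_hrv)) {
    subjects <- read_table_tsv(p_subj)
    summaries <- read_table_tsv(p_hrv)
    merged <- merge(summaries, subjects[, c("subject_id", "group")],
                    by = "subject_id")
    lines <- c(lines, "Group summaries by window (mean (SD), median [min, max])", "")
    for (m in c("hr_bpm", "rr_mean_s", "rmssd_s", "sdnn_s")) {
      lines <- c(lines, paste0("-- ", m))
      for (w in WINDOW_LABELS) {
        row <- sapply(c("FM", "control"), function(g) {
          x <- merged[[m]][merged$window == w & merged$group == g]
          x <- x[!is.na(x)]
          if (!length(x)) return("unavailable")
          sprintf("%s (%s), %s [%s, %s]", fmt3(mean(x)), fmt3(stats::sd(x)),
                  fmt3(stats::median(x)), fmt3(min(x)), fmt3(max(x)))
        })
        lines <- c(lines, sprintf("  %-9s FM: %s | control: %s",
                                  w, row[1], row[2]))
      }
    }
  } else {
    lines <- c(lines, "Group summaries: unavailable")
  }
  lines <- c(lines, "")
  gls_files <- list.files(out_dir, pattern = "^gls_.*\\.tsv$")
  if (length(gls_files)) {
    for (f in gls_files) {
      co <- read_table_tsv(file.path(out_dir, f))
      lines <- c(lines, paste0("Model: ", sub("\\.tsv$", "", f)),
                 sprintf("  %-32s %9s [%9s, %9s]  p=%s", co$term,
                         fmt3(co$estimate), fmt3(co$ci_low), fmt3(co$ci_high),
                         fmt3(co$p)), "")
    }
  } else {
    lines <- c(lines, "GLS models: unavailable", "")
  }
  p_cl <- file.path(out_dir, "cluster_model_selection.tsv")
  if (file.exists(p_cl)) {
    sel <- read_table_tsv(p_cl)
    lines <- c(lines, "Cluster model selection (total within-cluster SS):",
               sprintf("  %-28s d=%d k=%d  WSS=%s", sel$vars, sel$d, sel$k,
                       fmt3(sel$wss)))
    p_as <- file.path(out_dir, "cluster_assignments.tsv")
    if (file.exists(p_as)) {
      a <- read_table_tsv(p_as)
      lines <- c(lines, paste0("  chosen cluster sizes: ",
                               paste(table(a$cluster), collapse = "/")))
    }
    p_q <- file.path(out_dir, "cluster_questionnaires.tsv")
    if (file.exists(p_q)) {
      q <- read_table_tsv(p_q)
      lines <- c(lines, "", "Questionnaires across clusters (ANOVA):",
                 sprintf("  %-12s F=%8s  p=%s", q$variable, fmt3(q$F), fmt3(q$p)))
    }
  } else {
    lines <- c(lines, "Clustering: unavailable")
  }
  writeLines(lines, file.path(out_dir, "report.txt"))
  invisible(lines)
}
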