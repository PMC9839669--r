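# Synthetic cohort generation: subjects (covariates + questionnaires),
# per-subject autonomic profiles, numeric-rating-scale series, and the
# assembled cohort with ground-truth RR series and HRV summaries.

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Lognormal draw with the requested arithmetic mean and coefficient of
# variation (keeps group means exactly calibrated despite positivity).
rlnorm_mean_cv <- function(n, mean, cv) {
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Generate one subject record
#'
#' Covariates are drawn from group-calibrated distributions (FM BMI mean
#' 28.2 SD 5.87 vs control 24.7 SD 3.27; smoking probability 12/51 vs 2/31;
#' physical-activity probability 20/51 vs 16/31). Questionnaire scores are
#' drawn from cluster-graded distributions (anxiety and depressive-mood
#' locations increase from cluster 1 to 3) and clipped to instrument
#' ranges. Controls carry no cluster.
#'
#' @param id subject id.
#' @param group `"FM"` or `"control"`.
#' @param true_cluster cluster 1-3 for FM subjects; ignored for controls.
#' @param cfg a [default_sim_config()].
#' @param rng_seed integer seed.
#' @return a one-row data.frame.
#' @export
generate_subject <- function(id, group, true_cluster = NA_integer_,
                             cfg = default_sim_config(), rng_seed = 1L) {
  group <- match.arg(group, c("FM", "control"))
  if (group == "control") true_cluster <- NA_integer_
  if (group == "FM") stopifnot(true_cluster %in% 1:3)
  gi <- if (group == "FM") "fm" else "control"
  # questionnaire location index: clusters 1..3, controls in slot 4
  qi <- if (group == "FM") true_cluster else 4L
  q <- cfg$questionnaires
  with_seed(rng_seed, {
    age <- clip(stats::rnorm(1, cfg$age[[gi]][1], cfg$age[[gi]][2]), 18, 65)
    bmi <- clip(stats::rnorm(1, cfg$bmi[[gi]][1], cfg$bmi[[gi]][2]), 16, 55)
    smoker <- stats::runif(1) < cfg$smoker_prob[[gi]]
    active <- stats::runif(1) < cfg$active_prob[[gi]]
    lpa <- if (active) 7L else sample(3:6, 1)

    item_mean <- c(q$fiq_other[qi], q$fiq_other[qi], q$fiq_other[qi],
                   q$fiq_other[qi], q$fiq_pain[qi], q$fiq_other[qi],
                   q$fiq_other[qi], q$fiq_other[qi],
                   q$fiq_anxiety[qi], q$fiq_depression[qi])
    items <- clip(stats::rnorm(10, item_mean, q$fiq_item_sd), 0, 10)
    if (stats::runif(1) < q$fiq_missing_prob) items[3] <- NA
    if (stats::runif(1) < q$fiq_missing_prob) items[4] <- NA
    fiq_total <- mean(items, na.rm = TRUE) * 10

    pcs <- round(clip(stats::rnorm(1, q$pcs[qi], q$pcs_sd), 0, 52))
    pss <- round(clip(stats::rnorm(1, q$pss[qi], q$pss_sd), 0, 40))
    stai_a <- round(clip(stats::rnorm(1, q$stai_a[qi], q$stai_a_sd), 20, 80))
    stai_b <- round(clip(stats::rnorm(1, q$stai_b[qi], q$stai_b_sd), 20, 80))

    out <- data.frame(
      subject_id = id, group = group, true_cluster = true_cluster,
      age = age, bmi = bmi, smoker = smoker,
      lpa_score = lpa, physically_active = lpa >= 7,
      fiq_total = fiq_total, stringsAsFactors = FALSE)
    for (k in 1:10) out[[paste0("fiq_item", k)]] <- items[k]
    out$pcs <- pcs; out$pss <- pss
    out$stai_a <- stai_a; out$stai_b <- stai_b
    out
  })
}

#' Draw the autonomic profile for one subject
#'
#' Controls follow the control per-window HR means; FM subjects follow
#' their cluster's baseline HR with the control HR rise scaled by the
#' cluster attenuation factor (and further attenuated at the second stress
#' phase, capturing the more pronounced blunting under repeated stress).
#' Variability amplitudes are lognormal with group-calibrated means and
#' cluster-graded scaling for FM.
#'
#' @param group `"FM"` or `"control"`.
#' @param true_cluster cluster 1-3 for FM subjects.
#' @param cfg a [default_sim_config()].
#' @param rng_seed integer seed.
#' @return an [autonomic_profile()].
#' @export
draw_autonomic_profile <- function(group, true_cluster = NA_integer_,
                                   cfg = default_sim_config(), rng_seed = 1L) {
  group <- match.arg(group, c("FM", "control"))
  gi <- if (group == "FM") "fm" else "control"
  with_seed(rng_seed, {
    control_delta <- cfg$control_hr - cfg$control_hr[1]
    if (group == "control") {
      base <- clip(stats::rnorm(1, cfg$control_hr[1], cfg$base_hr_sd_control), 45, 150)
      alpha <- 1; beta <- 1
      var_scale <- 1
    } else {
      k <- true_cluster
      base <- clip(stats::rnorm(1, cfg$fm_cluster_base_hr[k], cfg$base_hr_sd_fm), 45, 150)
      alpha <- clip(stats::rnorm(1, cfg$fm_cluster_attenuation[k],
                                 cfg$attenuation_jitter_sd), 0, 1)
      beta <- clip(stats::rnorm(1, cfg$fm_cluster_stress2_factor[k],
                                cfg$attenuation_jitter_sd), 0, 1)
      var_scale <- cfg$fm_cluster_var_scale[k]
    }
    delta <- control_delta * alpha
    delta[5] <- control_delta[5] * alpha * beta   # stress2 repetition effect
    hr <- clip(base + delta, 40, 180)
    # RMSSD and SDNN co-vary strongly between subjects: draw one common
    # lognormal variability factor plus a small independent ratio jitter
    common <- rlnorm_mean_cv(1, 1, cfg$variability_cv)
    jit <- stats::rnorm(1, 0, 0.08)
    rmssd <- cfg$rmssd_mean[[gi]] * var_scale * common * exp(-jit / 2)
    sdnn <- cfg$sdnn_mean[[gi]] * var_scale * common * exp(jit / 2)
    # SDNN can never fall below the white-noise floor implied by RMSSD
    sdnn <- max(sdnn, rmssd / sqrt(2) * 1.01)
    resp <- clip(stats::rnorm(1, cfg$resp_freq_hz, cfg$resp_freq_sd), 0.15, 0.4)
    autonomic_profile(hr, rmssd, sdnn, resp_freq_hz = resp,
                      stress_var_scale = cfg$stress_var_scale)
  })
}

#' Generate the six numeric-rating-scale (NRS) ratings
#'
#' Ratings are collected at the start, between phases, and at the end of
#' the protocol (timepoints t1..t6). Stress ratings rise by
#' `cfg$nrs$stress_effect` at the two post-stress timepoints; pain ratings
#' are cluster-graded in level but carry no phase interaction. All ratings
#' are integer-rounded and clipped to 0-10.
#'
#' @param group `"FM"` or `"control"`.
#' @param true_cluster cluster 1-3 for FM subjects.
#' @param cfg a [default_sim_config()].
#' @param rng_seed integer seed.
#' @return data.frame with columns `timepoint` (1-6), `after` (window label
#'   completed before the rating), `nrs_pain`, `nrs_stress`.
#' @export
generate_nrs_ratings <- function(group, true_cluster = NA_integer_,
                                 cfg = default_sim_config(), rng_seed = 1L) {
  group <- match.arg(group, c("FM", "control"))
  qi <- if (group == "FM") true_cluster else 4L
  nrs <- cfg$nrs
  with_seed(rng_seed, {
    pain_lat <- stats::rnorm(1, nrs$pain_base[qi], 1)
    stress_lat <- stats::rnorm(1, nrs$stress_base[qi], 1)
    stress_bump <- c(0, 0, nrs$stress_effect, 0, nrs$stress_effect, 0)
    pain <- round(clip(pain_lat + stats::rnorm(6, 0, nrs$noise_sd), 0, 10))
    stress <- round(clip(stress_lat + stress_bump +
                           stats::rnorm(6, 0, nrs$noise_sd), 0, 10))
    data.frame(timepoint = 1:6,
               after = c("start", "relax1", "stress1", "relax2", "stress2", "relax3"),
               nrs_pain = pain, nrs_stress = stress)
  })
}

#' Generate a full synthetic cohort
#'
#' Subjects (default 51 FM allocated 9/21/21 across reactivity clusters by
#' largest remainder, plus 31 controls) each receive a ground-truth RR
#' tachogram, per-window truth HRV summaries, questionnaire scores, and
#' NRS ratings. Contaminated waveforms are not stored (a 20-min recording
#' is ~10 MB); they are regenerated deterministically per subject with
#' [cohort_waveform()].
#'
#' @param cfg a [default_sim_config()].
#' @param schedule a [phase_schedule()].
#' @return an object of class `hrv_cohort` with elements `subjects`
#'   (data.frame), `profiles`, `truth_rr` (lists keyed by subject id),
#'   `truth_hrv` (data.frame), `nrs` (data.frame), `seeds`, `config`,
#'   `schedule`.
#' @export
generate_cohort <- function(cfg = default_sim_config(),
                            schedule = build_default_schedule()) {
  validate_sim_config(cfg)
  n <- cfg$n_fm + cfg$n_control
  clusters <- allocate_clusters(cfg$n_fm, cfg$cluster_proportions)
  groups <- c(rep("FM", cfg$n_fm), rep("control", cfg$n_control))
  cl_all <- c(clusters, rep(NA_integer_, cfg$n_control))
  ids <- sprintf("S%03d", seq_len(n))
  seeds <- derive_seeds(cfg$master_seed, n)

  subjects <- vector("list", n)
  profiles <- vector("list", n)
  truth_rr <- vector("list", n)
  nrs_list <- vector("list", n)
  hrv_list <- vector("list", n)
  for (i in seq_len(n)) {
    subjects[[i]] <- generate_subject(ids[i], groups[i], cl_all[i], cfg,
                                      seeds[i, "subject"])
    profiles[[i]] <- draw_autonomic_profile(groups[i], cl_all[i], cfg,
                                            seeds[i, "subject"] + 1L)
    truth_rr[[i]] <- generate_rr_trajectory(profiles[[i]], schedule,
                                            seeds[i, "rr"])
    nrs_i <- generate_nrs_ratings(groups[i], cl_all[i], cfg, seeds[i, "nrs"])
    nrs_i$subject_id <- ids[i]
    nrs_list[[i]] <- nrs_i
    hrv_list[[i]] <- phase_summaries(truth_rr[[i]], schedule, ids[i])
  }
  names(profiles) <- names(truth_rr) <- ids
  out <- list(subjects = do.call(rbind, subjects),
              profiles = profiles,
              truth_rr = truth_rr,
              truth_hrv = do.call(rbind, hrv_list),
              nrs = do.call(rbind, nrs_list),
              seeds = seeds, config = cfg, schedule = schedule)
  class(out) <- "hrv_cohort"
  out
}

#' Regenerate the contaminated recording for one cohort subject
#'
#' Deterministic given the cohort's master seed: the clean ECG is
#' re-synthesised from the stored truth RR series and contaminated with
#' the subject's stored contamination seed.
#'
#' @param cohort an `hrv_cohort`.
#' @param subject_id subject id (or integer index).
#' @return a `waveform`.
#' @export
cohort_waveform <- function(cohort, subject_id) {
  stopifnot(inherits(cohort, "hrv_cohort"))
  i <- if (is.numeric(subject_id)) subject_id
       else match(subject_id, cohort$subjects$subject_id)
  stopifnot(!is.na(i))
  cfg <- cohort$config
  clean <- synthesize_ecg(cohort$truth_rr[[i]], fs = cfg$fs,
                          duration_s = cohort$schedule$total_dur_s,
                          width_s = cfg$qrs_width_s, amp_mv = cfg$qrs_amp_mv)
  contaminate(clean, cfg, cohort$seeds[i, "contaminate"])
}

#' @export
print.hrv_cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat(sprintf("Synthetic cohort: %d subjects (%d FM, %d control)\n",
              nrow(x$subjects), tab[["FM"]], tab[["control"]]))
  cl <- table(x$subjects$true_cluster[x$subjects$group == "FM"])
  cat("FM cluster sizes:", paste(cl, collapse = "/"), "\n")
  invisible(x)
}
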