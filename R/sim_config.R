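# Simulation configuration: cohort sizes, signal parameters, and the
# group/cluster calibration targets for autonomic and questionnaire
# structure. Defaults reproduce the study conditions: 51 fibromyalgia (FM)
# patients in three reactivity clusters of 9/21/21 and 31 healthy controls,
# 20-min recordings at 1000 Hz contaminated with 50 Hz mains interference
# and EMG-band noise at 0 dB QRS-band SNR.

#' Default simulation configuration
#'
#' Returns the full nested configuration for [generate_cohort()]. All
#' entries can be overridden via `...` (top-level keys) or by editing the
#' returned list.
#'
#' Autonomic calibration: per-window mean heart rates for controls and for
#' the three FM clusters are chosen so that the FM-wide means (weighted by
#' the 9/21/21 cluster allocation) match the observed group means (baseline
#' HR 72.3 bpm vs 64.5 bpm in controls, with an attenuated rise under
#' repeated cognitive stress). Short-term (RMSSD) and total (SDNN)
#' variability amplitudes are drawn per subject from lognormal
#' distributions whose group means match the observed baseline values.
#'
#' @param ... top-level overrides, e.g. `n_fm = 10`.
#' @return a list of class `sim_config`.
#' @export
default_sim_config <- function(...) {
  cfg <- list(
    n_fm = 51L,
    n_control = 31L,
    cluster_proportions = c(9, 21, 21) / 51,
    fs = 1000,
    master_seed = 20230113L,

    # signal contamination
    mains_freq_hz = 50,
    mains_harmonics = 2L,          # harmonics above the fundamental
    mains_amp_mv = 0.5,            # fundamental amplitude; harmonics decay by half
    emg_snr_db = 0,                # QRS-band (10-40 Hz) SNR of the EMG noise
    emg_band_hz = c(20, 450),
    drift_amp_mv = 0.3,
    drift_period_s = 60,

    # QRS template
    qrs_width_s = 0.012,           # Ricker shape parameter (~80 ms deflection)
    qrs_amp_mv = 1,

    # RR dynamics
    ramp_s = 10,
    resp_freq_hz = 0.25,
    resp_freq_sd = 0.03,
    resp_var_fraction = 0.25,      # share of total RR variance given to respiration
    stress_var_scale = 0.75,       # variability scaling during stress phases

    # per-window mean HR (bpm): baseline, relax1, stress1, relax2, stress2, relax3
    control_hr = c(64.5, 65.9, 77.5, 68.4, 77.7, 66.5),
    # FM cluster baseline HR means; weighted by 9/21/21 -> 72.3 bpm
    fm_cluster_base_hr = c(63, 72, 76.5),
    # stress-rise attenuation per cluster (multiplies the control HR rise)
    fm_cluster_attenuation = c(1.0, 0.80, 0.75),
    # extra attenuation at the second stress phase (repetition effect)
    fm_cluster_stress2_factor = c(1.0, 0.85, 0.70),
    attenuation_jitter_sd = 0.05,
    base_hr_sd_fm = 6,
    base_hr_sd_control = 7.8,

    # baseline variability targets (s): group means and within-group CV
    rmssd_mean = c(fm = 0.0286, control = 0.0363),
    sdnn_mean = c(fm = 0.0302, control = 0.0373),
    variability_cv = 0.6,
    # multiplicative cluster grading of FM variability (weighted mean ~ 1)
    fm_cluster_var_scale = c(1.8, 0.9, 0.75),
    rr_mean_target = c(fm = 0.844, control = 0.934),

    # covariates
    bmi = list(fm = c(28.2, 5.87), control = c(24.7, 3.27)),
    age = list(fm = c(45.1, 12.7), control = c(46.0, 11.7)),
    smoker_prob = c(fm = 12 / 51, control = 2 / 31),
    active_prob = c(fm = 20 / 51, control = 16 / 31),

    # questionnaire locations by cluster (FM c1, c2, c3) and control;
    # grading (cluster 3 > 2 > 1 for anxiety/depression) is a design choice,
    # not a published calibration
    questionnaires = list(
      fiq_anxiety = c(2.5, 6.5, 7.0, 0.8),
      fiq_depression = c(2.0, 4.5, 6.5, 0.5),
      fiq_pain = c(4.0, 6.5, 6.5, 0.5),
      fiq_other = c(4.0, 5.5, 6.0, 1.0),   # fatigue, refreshed, stiffness, items 1-2
      fiq_item_sd = 1.8,
      fiq_missing_prob = 0.4,              # items 3 and 4 only
      pcs = c(12, 20, 26, 6), pcs_sd = 8,
      pss = c(14, 20, 24, 10), pss_sd = 6,
      stai_a = c(32, 42, 46, 30), stai_a_sd = 8,
      stai_b = c(34, 44, 50, 31), stai_b_sd = 8
    ),

    # numeric rating scales at 6 timepoints (start, after each phase)
    nrs = list(
      stress_effect = 2,        # rise after a stress phase
      noise_sd = 0.8,
      pain_base = c(2.0, 4.5, 4.5, 0.5),   # clusters 1..3, control
      stress_base = c(2.0, 4.0, 4.5, 2.0)
    ),

    # mental-arithmetic stressor constants, recorded as provenance metadata
    stressor = list(n_series = 14L, digits_per_series = 10L,
                    digit_range = c(0L, 9L), false_feedbacks = 4L,
                    masking_noise_db = 60)
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_fm >= 1, cfg$n_control >= 1, cfg$fs >= 250,
            abs(sum(cfg$cluster_proportions) - 1) < 1e-9,
            all(cfg$cluster_proportions >= 0),
            length(cfg$control_hr) == 6,
            all(cfg$control_hr >= 40 & cfg$control_hr <= 180),
            all(cfg$fm_cluster_base_hr >= 40 & cfg$fm_cluster_base_hr <= 180),
            all(cfg$fm_cluster_attenuation >= 0 & cfg$fm_cluster_attenuation <= 1))
  invisible(cfg)
}

#' Deterministic cluster allocation by largest remainder
#'
#' Allocates `n` patients to clusters so that counts match the configured
#' proportions exactly up to rounding; the default 51-patient cohort yields
#' 9/21/21. Deterministic, so repeated runs reproduce identical counts.
#'
#' @param n number of patients.
#' @param proportions vector of cluster proportions summing to 1.
#' @return integer vector of cluster ids of length `n` (sorted).
#' @export
allocate_clusters <- function(n, proportions) {
  stopifnot(n >= 1, abs(sum(proportions) - 1) < 1e-9)
  q <- n * proportions
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  rep(seq_along(proportions), times = base)
}
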