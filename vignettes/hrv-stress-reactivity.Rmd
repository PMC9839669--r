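---
title: "Modelling HRV stress reactivity in fibromyalgia: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling HRV stress reactivity in fibromyalgia: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvreact)
```

## The scientific problem

Fibromyalgia (FM) is associated with autonomic dysfunction: patients tend
to show sympathetic dominance at rest (higher heart rate, lower heart
rate variability) together with a blunted autonomic response to acute
stress. A standard way to probe this is a fixed protocol of alternating
relaxation and cognitive stress (mental arithmetic) while recording the
electrocardiogram, summarising each protocol phase with time-domain HRV
measures, and asking (a) whether patients and controls respond
differently, and (b) whether patients split into subgroups with distinct
reactivity phenotypes.

`hrvreact` implements that full analysis chain as reusable, tested code:

1. a synthetic cohort generator with known ground truth at every stage,
2. ECG recovery from single-channel surface-EMG-grade recordings,
3. HRV summarisation over protocol windows,
4. baseline-adjusted generalized least squares (GLS) reactivity models,
5. constrained k-means stratification of patients by stress reactivity.

Because recordings of this kind are rarely shareable, the package is
exercised end-to-end on the synthetic cohort; the extraction and
modelling stages accept real data in EDF or delimited-text form through
the same interfaces.

## Protocol and windows

The default schedule is five contiguous 4-minute phases — relaxation,
stress, relaxation, stress, relaxation — 1200 s in total. Each phase is
summarised over an analysis window that skips the first 20 s and spans
180 s, so transient responses at phase onset do not dilute the phase
summary. Baseline is the first 30 s of the recording. The recording is
taken to start at the onset of the first relaxation phase, which places
the baseline window inside that phase's span but outside its analysis
window (the two windows share no time, so baseline and relax1 summaries
are computed on disjoint data). All windows are half-open and intervals
are assigned to windows by their end time, so no interval is counted
twice at a boundary.

## Time-domain HRV measures

For accepted RR intervals in a window the package computes:

* **RRmean** — arithmetic mean interval (s);
* **SDNN** — sample standard deviation (divisor $n-1$, the common
  HRV-software convention; divisor $n$ available);
* **RMSSD** — $\sqrt{\operatorname{mean}\,(\Delta RR)^2}$ over pairs of
  *consecutive accepted* intervals (a rejected interval breaks the
  chain);
* **HR** — mean of instantaneous rates $60/RR_i$ (bpm).

The HR convention deserves a note. Averaging $60/RR_i$ always gives a
value at least $60/\overline{RR}$ (Jensen's inequality), and tabulated
HR in this field consistently exceeds $60/\overline{RR}$ (e.g. a group
mean HR of 72.3 bpm alongside RRmean 0.844 s, whose reciprocal is 71.1).
The instantaneous convention is therefore the default; `mean_hr(...,
convention = "harmonic")` switches to $60/\overline{RR}$. Windows with
fewer than three beats yield missing values, never zeros. The internal
RR unit is seconds throughout, matching the magnitudes the measures are
reported in (RMSSD ~0.03 s); conversion to ms is a display concern.

## Synthetic cohort generator

The generator's defaults are the study conditions: 51 female FM patients
and 31 controls; the FM group is split into three reactivity clusters of
9/21/21 by deterministic largest-remainder allocation so default runs
reproduce those sizes exactly.

### RR dynamics

Each subject's tachogram is built sequentially: the next interval is

$$RR_{n} = m(t_n) + w(t_n)\,\bigl[a\,\sin(2\pi f_r t_n + \varphi) + e_n\bigr],
\qquad e_n = \phi\, e_{n-1} + \varepsilon_n,$$

where $m(t)$ is the phase-piecewise mean interval (linear 10-s ramps at
phase boundaries; no ramp model is implied by the protocol itself, a
ramp simply avoids discontinuities), $a\sin(\cdot)$ is one respiratory
(sinus-arrhythmia) component at $f_r \approx 0.25$ Hz, $e_n$ is AR(1)
noise, and $w(t)$ damps variability to 75% during stress phases
(stress reduces both RMSSD and SDNN in the tabulated phase summaries).
This is the minimal model in which short-term variability (RMSSD) and
total variability (SDNN) can be tuned separately: white-ish noise feeds
both, autocorrelation suppresses RMSSD relative to SDNN, and the
respiratory component adds band-limited power. Given per-subject targets
$(\text{RMSSD}^*, \text{SDNN}^*)$ the three parameters $(a, \phi,
\sigma_\varepsilon)$ are solved in closed form, with two finite-sample
corrections so that the *sample* statistics over the 30-s baseline
window are unbiased for the targets: the expected sample variance of an
AR(1) over $n$ beats is below the marginal variance (the window mean
absorbs slow fluctuation), and $E[s] < \sigma$ (the $c_4$ effect). The
correction is floored so pathological target ratios cannot inflate the
marginal variance without bound.

### Calibration

Per-window mean heart rates are the published group means: controls
(64.5, 65.9, 77.5, 68.4, 77.7, 66.5) bpm over (baseline, relax1,
stress1, relax2, stress2, relax3). FM cluster baseline means (63, 72,
76.5 bpm) are chosen so the 9/21/21-weighted mean is 72.3 bpm, and each
cluster's stress response is the control rise scaled by an attenuation
factor (1.0, 0.80, 0.75), with extra attenuation (×1.0, ×0.85, ×0.70)
at the second stress phase — stress-response blunting in patients is
more pronounced on repetition. The weighted FM means then reproduce the
published FM phase profile (e.g. stress1 ≈ 82.9, stress2 ≈ 81.1 bpm)
and the implied group-by-time interaction at stress2 of about −4.4 bpm.
Variability targets are lognormal between subjects (CV 0.6, matching
the tabulated dispersion) with group means at the published baseline
values and strong RMSSD-SDNN coupling (a common factor plus a small
ratio jitter), since the two measures co-vary strongly across people.

Two generator choices are deliberately *not* taken from the published
tables. First, the within-cluster baseline-HR SD is 6 bpm, below the
total FM SD of 12.7, because the published SD mixes between- and
within-cluster spread; reusing it within clusters would make the
clusters unrecoverable by construction. Second, questionnaire locations
(FIQ items, PCS, PSS, STAI) are free configuration defaults graded
cluster 3 > 2 > 1 for anxiety and depressive mood, with controls low;
only significance patterns, not means, are published, so no numeric
calibration is claimed. Mean HR and RRmean cannot both be matched
exactly by any single tachogram model (the instantaneous-HR convention
makes mean HR exceed the reciprocal RRmean by a factor that depends on
the variability), so the generator parametrises by HR and accepts a
~1–2% RRmean discrepancy, well inside the 5% calibration tolerance the
tests enforce.

The mental-arithmetic stressor's constants (14 series of ten digits 0–9,
four false feedbacks, 60 dB masking noise) are recorded as provenance
metadata in the configuration; no auditory stimulus is simulated.

### ECG synthesis and contamination

A beat is a Ricker (negative second Gaussian derivative) deflection with
shape parameter 12 ms (~80 ms visible QRS-like complex, 1 mV peak).
Recordings are contaminated with (a) Gaussian noise band-limited to
20–450 Hz — the surface-EMG band — scaled so the QRS-band (10–40 Hz)
SNR is 0 dB, (b) mains interference at 50 Hz plus two harmonics with
halving amplitudes (0.5 mV fundamental, which dominates the raw
spectrum's peak), and (c) slow sinusoidal baseline drift (0.3 mV,
60 s). What the generator does **not** emulate: true EMG burst
structure (muscle activity is nonstationary and impulsive), electrode
motion artifacts, ectopic beats, or morphological ECG variation.
Passing tests therefore demonstrate correctness of the chain under
realistic *stationary* noise, not robustness to every clinical artifact.

## ECG recovery chain

`extract_rr()` runs: detrend (mean removal; optional linear) →
powerline-band flattening → 10–40 Hz Butterworth bandpass →
embedding-PCA enhancement → QRS detection → RR cleaning.

**Spectral flattening.** Candidate mains frequencies (50, 100, 150 Hz by
default; configurable, or an explicit band list for the manual
workflow) are flagged when the periodogram's mean power in the 1-Hz
band exceeds 3× the mean of the two flanking 0.5-Hz bands. Flagged
bands are treated in the frequency domain: bin magnitudes inside the
band are rescaled so the band's mean power equals the flank mean,
phases untouched, conjugate symmetry maintained. Power outside the
treated band is conserved bit-for-bit (those bins are untouched), and
the operation is idempotent up to estimator noise.

**Bandpass.** Third-order Butterworth, 10–40 Hz, applied
forward-backward by default so filtering is zero-phase and beat times
are not lag-shifted (a single-pass causal mode exists for streaming
use).

**PCA enhancement.** The single best channel is carried forward, so the
principal component analysis operates on a time-delay embedding of that
channel (lag 1). For long signals the embedding covariance is the
Toeplitz matrix of the autocovariance, and the rank-1 reconstruction
along the first eigenvector reduces, after diagonal averaging, to
zero-phase filtering with the eigenvector's autocorrelation — a
data-learned matched filter for the dominant transient (the QRS). This
is implemented directly (autocovariance → 80×80 eigenproblem → FFT
convolution), avoiding any large embedding matrix. The embedding span
default is 80 ms: it should cover the QRS complex, and spans well below
that (e.g. 25 ms) leave too little matched-filter gain at 0 dB in-band
SNR — in our measurements positive predictive value drops from ~99.5%
to ~91%. A cross-channel PCA mode (`isolate_ecg_pca_multichannel`) is
provided for multichannel recordings.

**QRS detection.** Square, integrate over a 150-ms moving window, accept
integrated local maxima above 0.4× the running median of the last eight
accepted peak heights, under a 250-ms refractory period (stronger peak
wins inside the refractory window); the beat time is the local maximum
of the enhanced signal near the detection. Two rhythm-correction passes
then repair the rare residual errors: intervals shorter than 0.7× the
local median RR drop their weaker endpoint, and gaps longer than 1.6×
the local median are searched for one missed beat at a time. At the
default noise level this chain recovers ≥99% of beats with ≥99%
precision and sub-millisecond median timing error.

**RR cleaning.** Three rules flag (never modify) intervals: outside
[0.3, 2.0] s; deviating >30% from the running 5-interval median; and an
adaptive rule flagging deviations beyond 3× the recording's own local
robust scale (MAD of the deviations from the running median). The third
rule exists because a beat mistimed by ~100 ms changes its two
neighbouring intervals by ~12% — invisible to the 30% rule, yet enough
to inflate a low-variability window's RMSSD several-fold. Flagged
intervals are excluded from all metrics and break the RMSSD chain.
Residual limitation: in 3-min stress windows with true RMSSD near 7 ms,
beat-timing jitter still inflates extracted RMSSD by ~10% (each ms of
timing error contributes $\sqrt{6}\,\sigma_t$ to the RMSSD scale);
HR and RRmean are essentially exact, SDNN within a few percent.

**Channel selection** (the automated analogue of visual inspection)
scores each channel by the coefficient of variation of a trial
extraction's accepted RR intervals, with QRS-band SNR and lower index as
tie-breaks.

## Reactivity models

For each outcome (HR, RRmean, RMSSD, SDNN) the long table has one row
per subject and phase, the first relaxation phase as the reference
level, and the subject's baseline value of the same outcome as a
covariate:

$$y \sim \text{group} \times \text{time} + \text{baseline}
\;(+\; \text{BMI} + \text{smoking} + \text{physical activity}).$$

Estimation is feasible GLS with an exchangeable (compound-symmetric)
within-subject correlation: iterate ordinary/generalized least squares
with a moment estimate of $\rho$ from residual cross-products until
$\rho$ converges (tolerance 1e-6, cap 50 iterations). Exchangeability is
the minimal structure that justifies GLS over OLS for a handful of
repeated phases; an AR-by-phase structure would add parameters the five
phases cannot support. Wald intervals use a $t$ reference with residual
degrees of freedom ($n_{obs} - p$) — with 400+ observations the choice
of df convention is immaterial. With $\rho$ fixed at 0 the fit equals
OLS exactly (tested to 1e-10), and on balanced data the coefficients
match `nlme::gls` with a compound-symmetry correlation to machine
precision. Under a null simulation at the study's size (51+31 subjects,
$\rho = 0.3$) the stress2-interaction Wald test rejects at 3.9–5% —
nominal within Monte-Carlo error. Covariates that are constant in the
analysed subset (e.g. no smokers in a small cohort) are dropped with a
message rather than poisoning the design matrix. Missing phases are
dropped listwise per outcome; subjects without a baseline are excluded
with a warning.

Two-group baseline comparisons report both Student's t and Mann-Whitney
(both conventions appear in this literature, and they can disagree);
categorical covariates use the Yates-corrected χ² — the correction is
pinned by the fact that only the corrected statistic reproduces the
published p-values (0.091, 0.386) from the published 2×2 counts.
Cluster contrasts use one-way ANOVA with Tukey HSD.

## Patient stratification

Clustering variables are the baseline→stress2 changes
$\Delta HR$ and $\Delta RR_{mean}$, z-transformed. The sample-size rule
$n \ge 10\,d\,k$ (d variables, k clusters) restricts the search; for 51
patients the published feasible set is both variables with k = 2, or one
variable with k = 2 or 3. That set stops at k = 3 even though the
literal inequality admits (d = 1, k = 5) at n = 51, so both modes are
exposed: `mode = "published"` (default) reproduces the published set,
`mode = "rule"` applies the inequality literally. Each configuration is
clustered by k-means (Lloyd iterations from k-means++ starts, 100
restarts, deterministic by seed, empty clusters reseeded with the
farthest point), and the minimum total within-cluster sum of squares
across configurations selects the model — comparable across dimensions
only because all variables are z-scored first, which is a scale
convention, not a scale-free criterion. Ties prefer fewer variables,
then fewer clusters. On small point sets the implementation attains the
exhaustive-enumeration optimum in ≥99% of seeded runs.

Cluster labels are re-ordered by ascending mean baseline HR, so
"cluster 1" is always the least tachycardic (most control-like) cluster
and reports are invariant to k-means label permutation.
Characterisation compares questionnaire scores across clusters (ANOVA +
Tukey; items with >20% missingness are excluded — the two FIQ items
about sick leave and work ability carry high missingness by
construction) and refits HRV and NRS pain/stress trajectories with the
sparse cluster model $y \sim \text{cluster} \times \text{time} +
\text{baseline}$.

A caution the tests make explicit: recovery of the true cluster labels
depends on mode separation. With three Gaussian modes 2 within-SD apart
the Bayes-optimal assignment already misclassifies ~16% per adjacent
boundary, capping the adjusted Rand index near 0.6 — no algorithm can
reach ARI 0.9 there. Recovery at ARI ≥ 0.9 in ≥95% of replicates
requires roughly 5–6 SD separation, and the test suite demonstrates
both regimes. The default cohort's clusters 2 and 3 deliberately
overlap (≈1 within-SD apart in $\Delta RR_{mean}$), mirroring how
tentative the patient-subgroup structure is in practice; accordingly the
minimum-WSS selection on a default cohort may pick $\Delta HR$ rather
than $\Delta RR_{mean}$ at k = 3 — the two candidates differ by a few
percent of WSS and express the same underlying 3-cluster structure.

## Numerical and I/O choices

* All randomness flows from one master seed through per-subject,
  per-stage derived seeds; cohort generation, contamination and the
  full pipeline are bit-reproducible (tested by digest equality of two
  complete runs).
* Signals are exchanged as EDF (16-bit, the clinical-physiology norm; a
  minimal reader/writer is included since no installed package provides
  one) or two-column delimited text with a uniformity check on the time
  column (relative tolerance 1e-4; jittered timestamps are refused
  rather than resampled).
* Degenerate inputs fail loudly and early: zero-variance z-transforms,
  k above the number of distinct points, rank-deficient designs (with
  the aliased columns named), bands touching 0 or Nyquist, sampling
  rates at or below twice the upper bandpass corner.
* Test problem sizes: metric oracles run on 10³ random series; the
  type-I-error simulation uses 1000 replicates at the study's size;
  generator recovery uses 200 replicate cohorts of truth tachograms;
  extraction fidelity uses 20 full-length contaminated recordings; the
  calibration checks use ~1.5×10³ simulated subjects.

## Known limitations

* The EMG noise model is stationary and Gaussian; real surface-EMG
  contamination is burst-like and can locally overwhelm the QRS band.
* Extracted RMSSD carries an upward bias of order 10% in
  low-variability windows at 0 dB in-band SNR (timing-jitter floor);
  conclusions that hinge on stress-window RMSSD levels should use the
  truth-bypass mode or cleaner recordings.
* The feasible GLS uses a moment estimator for $\rho$, not ML/REML;
  on balanced data the difference is negligible, under heavy
  missingness ML would be preferable.
* Questionnaire scores are generated conditionally independent of HRV
  given cluster membership; any real within-subject coupling beyond
  cluster structure is not emulated, so cross-domain correlations in
  synthetic cohorts understate reality.
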