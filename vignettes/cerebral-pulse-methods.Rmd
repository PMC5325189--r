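---
title: "Measuring cerebral pulse amplitude and arterial compliance from diffuse optical recordings"
author: "cerepulse authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cerebral pulse amplitude and arterial compliance from diffuse optical recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cerepulse)
```

## The measurement

Every heartbeat sends a pressure wave through the cerebral arteries.
Near-infrared light traversing the scalp and cortex is absorbed a
little more when arterial blood volume transiently rises, so the AC
intensity of a frequency-domain optical channel carries a small
cardiac-locked oscillation — a cerebral photoplethysmogram.  Averaging
many beats time-locked to the EKG R wave yields, per channel, a clean
*pulse waveform* from which this package derives two indices of
cerebrovascular health:

* **Pulse amplitude** — the mean baselined percent-change intensity in
  the systolic window, 384–538 ms post-R.  It scales with the local
  pulsatile blood-volume excursion and acts as a proxy for cerebral
  pulse pressure.
* **Arterial compliance** — a pure *shape* index of the diastolic limb.
  The segment between the systolic peak and the diastolic trough is
  affinely normalized to the unit square (time 0–1, amplitude 1 at the
  peak, 0 at the trough); compliance is the area under that normalized
  curve minus 0.5, the area of a straight oblique line.  A linear decay
  scores exactly 0; a decay that holds near the systolic level for the
  whole diastole approaches +0.5 (elastic recoil sustains diastolic
  flow); a fast convex collapse approaches −0.5 (a stiff vessel).  By
  construction the index is invariant to any positive affine amplitude
  transform and to uniform time dilation, which decouples it from pulse
  amplitude and from heart rate.

The processing chain is: EKG band-pass (0.5–40 Hz, zero-phase) →
standardized-threshold R-wave detection with interbeat-interval vetting
→ optical normalization to percent change about each channel's mean →
optional cardiac band-pass (0.5–5 Hz) → artifact masking → R-locked
epoch extraction and averaging → baselining to the 128–256 ms
early-diastole window → per-channel indices → ROI aggregation (global
Talairach box X ∈ [−45, 45], Y ∈ [−80, 50]; frontoparietal BA9+BA7;
visual BA17+BA18), with channels restricted to source–detector
distances in the closed 2–6 cm band.

## The synthetic cohort

No raw human recordings ship with the package.  Instead, `sim_config()`
/ `simulate_cohort()` generate cohorts with known ground truth so every
estimator can be validated end to end:

* **Beats** — lognormal interbeat jitter (default 60 bpm, CV 5%),
  clamped to the 0.4–2 s plausibility band; 360 s recordings carry well
  over the ~100 epochs needed for a stable average.
* **Pulse kernel** — zero until 300 ms post-R, a half-cosine upstroke
  peaking at 450 ms (inside the 384–538 ms systolic window), then a
  diastolic decay reaching zero at 900 ms.  The decay is
  `d(u) = (e^{-ku} − e^{-k}) / (1 − e^{-k})` with
  `k = k_max (2s − 1)` for stiffness `s ∈ [0, 1]`; `s = 0.5` is an
  exactly straight line (compliance 0) and `k_max = 6` spans compliance
  ±0.336, bracketing the full plausible range.  The closed form
  `kernel_compliance()` supplies the ground truth the pipeline must
  recover.
* **Amplitude and noise** — the kernel is scaled by a per-subject pulse
  pressure (percent of mean intensity, growing mildly with age) and
  buried in white noise (default SD 0.5%, i.e. raw single-beat SNR
  around 2:1, so that averaging >100 epochs exceeds 20:1).
* **Cohort structure** — ages spread evenly over six decades (18–77);
  ground-truth stiffness rises with age (0.006/yr) and falls with the
  physical-activity score (−0.04/SD), with ±0.03 regional offsets
  between the frontoparietal and visual channel groups; covariates
  (gender, BMI, resting HR, activity, blood pressures, brain volumes,
  cognitive scores) are drawn with realistic central values and
  age trends so the statistical battery has plausible material.
* **Artifacts and ectopy** — motion artifacts (a 5% boxcar baseline
  step plus 10% spikes) and ectopic beats are injected only in declared
  windows recorded in the ground truth, so rejection logic is tested
  against known labels; defaults are clean recordings.

What the generator deliberately does *not* emulate: photon transport
(no Monte-Carlo/diffusion modelling; channel "depth" is the standard
midpoint heuristic), two-wavelength chromophore separation, realistic
EKG morphology beyond R-peak placement, and pink/physiological noise
(Mayer waves, respiration) beyond the filtered band.  Passing tests
therefore demonstrate correctness of the estimators under the stated
signal model, not robustness to every artifact of real scalp optics.

## Numerical choices

* **Filtering** is zero-phase (forward–backward Butterworth, order 4
  per stage, realized as a low-pass/high-pass cascade for numerical
  stability at low band edges), so R-peak latency and waveform timing
  are not shifted.
* **R-wave detection** thresholds the standardized filtered trace at
  z = 3 (scale-invariant), de-duplicates candidate peaks within a
  200 ms refractory window (taller peak wins), and removes peaks
  creating intervals below 0.4 s, keeping the taller of the pair.  The
  interbeat band 0.4–2 s and the threshold are configurable per
  subject; every discarded candidate carries exactly one reason code.
* **Epoch resampling** onto the common post-R grid uses a cubic spline
  through each channel's series rather than linear interpolation.
  Averaging linearly interpolated epochs over random beat phases
  convolves the waveform with a 25.6 ms triangular window and deforms
  the systolic crest by ~2.4% of peak; spline resampling keeps the
  recovered kernel within 1% of the injected one.
* **Peak anchoring** runs on a 10× spline-oversampled copy of the
  averaged waveform.  On the native 25.6 ms grid the sample argmax can
  sit a quarter of a crest-width from the true systolic peak, which
  biases compliance by up to ~0.035; sub-sample refinement brings the
  noiseless pipeline within 0.02 of the generator's ground truth.
  Amplitude stays a plain mean over the native in-window samples, and
  the compliance integral itself is a trapezoid on whatever grid it is
  given.  Ties in argmax/argmin break to the earliest sample.
* **Baselining** subtracts the mean over the fixed 128–256 ms window
  (the early-diastole trough of the locked beat); no peak search is
  involved, so it is exactly idempotent.
* **Diastolic reference** — the waveform minimum between the systolic
  peak and a 900 ms search cap (configurable), matching the monotone
  normalized segment the index is defined on.  Degenerate inputs (flat
  waveform, inverted segment, <3 samples) are flagged per unit rather
  than aborting a batch; normalized samples escaping [0, 1] under noise
  are integrated as-is and flagged `out_of_range`.
* **Distance band** 2–6 cm is treated as a closed interval; box-ROI
  membership is closed on the box edges and ignores depth (only
  Talairach X and Y are declared for a montage).

Known estimator limitation: because the systolic and diastolic anchors
are an extremum of a (residually) noisy averaged waveform, anchor
values are biased outward by roughly the waveform's residual noise SD;
at default settings (noise SD 0.5%, >300 epochs) this depresses
compliance by a few hundredths uniformly across subjects.  It is nearly
constant within a cohort, so rank-order analyses are unaffected — the
package recovers the stiffness ordering of a 50-subject cohort with
|Spearman ρ| > 0.99 — but absolute compliance values should be compared
only between identically processed recordings.  The 0.5–5 Hz optical
band-pass similarly reshapes the waveform slightly (it removes kernel
harmonics above 5 Hz); shape-sensitive comparisons between studies
should use identical filter settings.

## The statistical battery

`run_study_analyses()` executes a declarative plan of correlation
analyses over the cohort table, with per-analysis directional tails
(one-tailed tests mirror a-priori directional hypotheses; the runner
reports both tails), single-pass |Z| > 2.5 outlier exclusion against
the sample mean and SD (no re-standardization after removal), and
partial correlation by two-stage least-squares residualization
(`df = n − 2 − k`).  Estimated cardiorespiratory fitness is a linear
combination of gender, age, BMI, resting heart rate, an activity score
and a constant (METs); the default weights follow the published
non-exercise estimation equations (Jurca et al., 2005, Am J Prev Med)
and are supplied as a configuration object, not hard-coded.
Heteroscedasticity against age uses the squared standardized residuals
of the index regressed on age, correlated with age.  Mediation
(`mediation_simple()`) fits the a/b paths by OLS and bootstraps the
indirect effect `a·b` over subject resamples with a percentile CI
(default 5000 samples; bias-corrected intervals were deliberately not
made the default because the plain percentile interval is the simplest
interval consistent with "n bootstrap samples" and its null coverage
verifies at 95% ± 3% in the acceptance suite).  Covariates are
residualized out of x, m and y before the paths are fit.  Missing data
are handled by complete-case analysis per comparison.

Open choices resolved here (and why): the "flat line" endpoint of the
compliance scale is read as flat *at the systolic level* (that is the
only reading consistent with the printed value +0.5); aggregates
include QC-flagged units by default (exclusion is a flag away, but the
default mirrors plain voxel averaging); interbeat plausibility bounds
and the detection threshold are engineering defaults exposed in the
configuration because no canonical values exist.

## Problem sizes used in the shipped checks

The test-suite and acceptance checks run, by choice, at desk scale: 360
s recordings at 39.0625 Hz with 16 channels; 10 noiseless subjects for
pipeline-recovery checks; 50 subjects at default noise for the
stiffness-monotonicity check; 500 simulated datasets × 1000 bootstrap
samples for mediation coverage; 100–200 replicates at n = 500 for the
heteroscedasticity power/size checks.  These sizes make every check
reproducible in minutes on one core while keeping Monte-Carlo error
well inside the asserted tolerances.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_subjects = 12, seed = 42)
cohort <- process_cohort(cfg)
cor(cohort$true_stiffness, cohort$est_compliance, method = "spearman")

plan <- data.frame(x = "age_years", y = "est_compliance",
                   tail = "negative", outlier_on = "y")
run_study_analyses(cohort, plan)
```
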