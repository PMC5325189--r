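# Simulation configuration and the per-subject ground truth container.

#' Simulation configuration
#'
#' Defaults mirror the acquisition this package targets: 360 s of
#' multichannel optical recording per subject at 39.0625 Hz with a
#' simultaneous 1000 Hz one-lead EKG, a cohort spread evenly across six
#' age decades (18--77), and a resting heart rate near 60 bpm with 5%
#' lognormal interbeat variability, so a recording carries well over 100
#' pulse epochs.
#'
#' Ground-truth generative dials:
#' * `stiffness_base`, `age_stiffness_slope` (per year, positive: older
#'   subjects are stiffer), `fitness_stiffness_slope` (per SD of the
#'   physical-activity score, negative: fitter subjects are more
#'   compliant), `stiffness_sd` (between-subject residual), and
#'   `regional_stiffness_offsets` added to frontoparietal/visual channel
#'   groups.  Stiffness is clamped to \[0.02, 0.98\].
#' * `pulse_pressure_au` is the subject's pulsatile amplitude in percent
#'   of mean light intensity; it grows with age at
#'   `pulse_pressure_age_slope` and is independent of stiffness.
#' * `noise_sd_au` is additive white channel noise (percent units).  The
#'   default 0.5 gives a raw single-beat SNR of roughly 2:1, so that
#'   averaging >100 epochs comfortably exceeds 20:1.
#' * `artifact_rate_per_min` and `ectopic_rate_per_min` are 0 by default;
#'   motion artifacts and ectopic beats are injected explicitly, with
#'   their windows/times recorded in the ground truth, so rejection logic
#'   can be tested against known labels.
#'
#' @param n_subjects Number of subjects (default 48, 8 per decade).
#' @param duration_s Recording length per subject in seconds.
#' @param fs_optical_hz,fs_ekg_hz Sampling rates.
#' @param n_channels Channels per montage (default 16, 4 per region).
#' @param age_range Two-element age range in years.
#' @param hr_bpm Mean resting heart rate.
#' @param hr_cv Coefficient of variation of the lognormal interbeat jitter.
#' @param mean_intensity_au Mean channel light intensity (a.u.).
#' @param pulse_pressure_au Baseline pulsatile amplitude (% of mean).
#' @param pulse_pressure_age_slope Amplitude increase per year of age.
#' @param noise_sd_au Channel noise SD (% of mean intensity).
#' @param ekg_noise_sd EKG additive noise SD (fraction of R amplitude).
#' @param rise_start_ms,systole_ms,diastole_ms Kernel timing: onset of
#'   the systolic upstroke, systolic peak (inside the 384--538 ms
#'   amplitude window), and diastolic endpoint.
#' @param k_max Maximum |exponential rate| of the diastolic decay;
#'   stiffness s maps to `k = k_max * (2 s - 1)`.
#' @param stiffness_base,age_stiffness_slope,fitness_stiffness_slope,stiffness_sd
#'   Ground-truth stiffness model (see Details).
#' @param regional_stiffness_offsets Named numeric, offsets added to the
#'   `frontoparietal` and `visual` channel groups.
#' @param artifact_rate_per_min,artifact_duration_s Motion-artifact
#'   injection rate and window length.
#' @param ectopic_rate_per_min Ectopic-beat injection rate.
#' @param seed Integer seed; every generator is deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 48,
                       duration_s = 360,
                       fs_optical_hz = 39.0625,
                       fs_ekg_hz = 1000,
                       n_channels = 16,
                       age_range = c(18, 77),
                       hr_bpm = 60,
                       hr_cv = 0.05,
                       mean_intensity_au = 1000,
                       pulse_pressure_au = 1.0,
                       pulse_pressure_age_slope = 0.01,
                       noise_sd_au = 0.5,
                       ekg_noise_sd = 0.05,
                       rise_start_ms = 300,
                       systole_ms = 450,
                       diastole_ms = 900,
                       k_max = 6,
                       stiffness_base = 0.5,
                       age_stiffness_slope = 0.006,
                       fitness_stiffness_slope = -0.04,
                       stiffness_sd = 0.04,
                       regional_stiffness_offsets = c(frontoparietal = 0.03,
                                                      visual = -0.03),
                       artifact_rate_per_min = 0,
                       artifact_duration_s = 2,
                       ectopic_rate_per_min = 0,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_subjects < 1) stop("n_subjects must be positive")
  if (cfg$fs_optical_hz <= 0 || cfg$fs_ekg_hz <= 0) {
    stop("sampling rates must be positive")
  }
  if (cfg$n_channels < 1) stop("n_channels must be at least 1")
  if (cfg$duration_s <= 0) stop("duration_s must be positive")
  if (cfg$duration_s * cfg$hr_bpm / 60 < 100 && cfg$duration_s >= 360) {
    stop("defaults must allow at least 100 beats")
  }
  if (!(cfg$rise_start_ms < cfg$systole_ms &&
        cfg$systole_ms < cfg$diastole_ms)) {
    stop("kernel timing must satisfy rise_start < systole < diastole")
  }
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from YAML
#'
#' Any field of [sim_config()] may be given; the rest take defaults.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  raw <- lapply(raw, function(x) if (is.list(x)) unlist(x) else x)
  do.call(sim_config, raw)
}

#' Per-subject ground truth
#'
#' @param subject_id Label.
#' @param beat_times_s Strictly increasing normal beat times (s).
#' @param stiffness Named per-channel stiffness in \[0, 1\].
#' @param pulse_pressure_au Subject pulsatile amplitude (% of mean).
#' @param noise_sd_au Channel noise SD (% of mean).
#' @param artifact_windows_s List of `c(start, end)` contaminated windows.
#' @param ectopic_times_s Injected ectopic beat times (s); these violate
#'   the interbeat plausibility band on purpose.
#' @param ibi_band_s Plausibility band the normal beats satisfy.
#' @return A list of class `ground_truth`.
#' @export
ground_truth <- function(subject_id, beat_times_s, stiffness,
                         pulse_pressure_au, noise_sd_au,
                         artifact_windows_s = list(),
                         ectopic_times_s = numeric(0),
                         ibi_band_s = c(0.4, 2)) {
  if (is.unsorted(beat_times_s, strictly = TRUE)) {
    stop("beat_times_s must be strictly increasing")
  }
  if (length(beat_times_s) > 1) {
    ibi <- diff(beat_times_s)
    if (any(ibi < ibi_band_s[1] | ibi > ibi_band_s[2])) {
      stop("interbeat intervals of normal beats must lie in [",
           ibi_band_s[1], ", ", ibi_band_s[2], "] s")
    }
  }
  if (any(stiffness < 0 | stiffness > 1)) stop("stiffness must be in [0, 1]")
  if (pulse_pressure_au <= 0) stop("pulse_pressure_au must be positive")
  structure(list(subject_id = subject_id, beat_times_s = beat_times_s,
                 stiffness = stiffness,
                 pulse_pressure_au = pulse_pressure_au,
                 noise_sd_au = noise_sd_au,
                 artifact_windows_s = artifact_windows_s,
                 ectopic_times_s = ectopic_times_s),
            class = "ground_truth")
}

#' Simulate a beat train with lognormal heart-rate variability
#'
#' @param config A `sim_config`.
#' @param hr_bpm Mean heart rate (default from config).
#' @return Strictly increasing beat times in `[0, duration_s]`, with
#'   intervals clamped to the plausibility band.
#' @export
simulate_beat_times <- function(config, hr_bpm = config$hr_bpm) {
  m <- 60 / hr_bpm
  sigma <- sqrt(log(1 + config$hr_cv^2))
  mu <- log(m) - sigma^2 / 2
  n_max <- ceiling(config$duration_s / m * 1.5) + 10
  ibi <- pmin(pmax(exp(rnorm(n_max, mu, sigma)), 0.4), 2)
  t <- 0.5 + cumsum(c(0, ibi))
  t[t <= config$duration_s - 1e-9]
}
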