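# Cohort-level generation: a synthetic montage with Brodmann-area
# labels, subject covariates, ground-truth stiffness, and per-subject
# recordings.

#' Build a synthetic optical montage
#'
#' Channels are laid out in four region groups on a flat scalp plane
#' (z = 80 mm): frontal BA9, parietal BA7, and occipital BA17/BA18, all
#' inside the global Talairach box.  Source and detector sit 30 mm apart
#' (3 cm, inside the 2--6 cm analysis band) and the Talairach mapping is
#' the declared identity placement of the montage plane.
#'
#' @param n_channels Total channels (distributed across the 4 regions).
#' @return A [channel_geometry()] with `region_label` and `region_group`
#'   (`"frontoparietal"` or `"visual"`) columns.
#' @export
make_montage <- function(n_channels = 16) {
  if (n_channels < 1) stop("n_channels must be at least 1")
  regions <- data.frame(
    region_label = c("BA9", "BA7", "BA17", "BA18"),
    region_group = c("frontoparietal", "frontoparietal", "visual", "visual"),
    cx = c(0, 0, -10, 10), cy = c(40, -35, -70, -70),
    stringsAsFactors = FALSE)
  per <- rep(n_channels %/% 4, 4) + c(rep(1, n_channels %% 4),
                                      rep(0, 4 - n_channels %% 4))
  rows <- list()
  ch <- 0
  for (r in seq_len(4)) {
    if (per[r] == 0) next
    off <- seq(-12, 12, length.out = max(per[r], 2))[seq_len(per[r])]
    for (i in seq_len(per[r])) {
      ch <- ch + 1
      mx <- regions$cx[r] + off[i]
      my <- regions$cy[r] + (i %% 2) * 6 - 3
      rows[[ch]] <- data.frame(
        channel_id = sprintf("ch%02d", ch),
        sx = mx - 15, sy = my, sz = 80, dx = mx + 15, dy = my, dz = 80,
        region_label = regions$region_label[r],
        region_group = regions$region_group[r],
        stringsAsFactors = FALSE)
    }
  }
  channel_geometry(do.call(rbind, rows))
}

# Evenly spread ages across six decade bins (ties filled round-robin),
# mirroring recruitment of equal numbers per decade.
cohort_ages <- function(n, age_range) {
  bins <- seq(age_range[1], age_range[2], length.out = 7)
  per <- rep(n %/% 6, 6) + c(rep(1, n %% 6), rep(0, 6 - n %% 6))
  unlist(lapply(seq_len(6), function(b) {
    if (per[b] == 0) return(numeric(0))
    seq(bins[b] + 0.5, bins[b + 1] - 0.5, length.out = per[b])
  }))
}

# Subject-level ground-truth stiffness and covariates.
cohort_covariates <- function(config) {
  n <- config$n_subjects
  age <- cohort_ages(n, config$age_range)
  gender <- rep_len(c("F", "M"), n)
  bmi <- pmin(pmax(rnorm(n, 26, 4), 18), 40)
  resting_hr <- pmin(pmax(rnorm(n, config$hr_bpm + 8, 8), 45), 95)
  activity_score <- sample(0:7, n, replace = TRUE)
  act_z <- if (n > 1 && sd(activity_score) > 0) {
    (activity_score - mean(activity_score)) / sd(activity_score)
  } else rep(0, n)
  mid_age <- mean(config$age_range)
  stiff <- config$stiffness_base +
    config$age_stiffness_slope * (age - mid_age) +
    config$fitness_stiffness_slope * act_z +
    rnorm(n, sd = config$stiffness_sd)
  stiff <- pmin(pmax(stiff, 0.02), 0.98)
  pp <- pmax(config$pulse_pressure_au +
               config$pulse_pressure_age_slope * (age - mid_age) +
               rnorm(n, sd = 0.1), 0.2)
  systolic <- 105 + 0.45 * (age - 18) + 8 * rnorm(n)
  diastolic <- 68 + 0.10 * (age - 18) + 6 * rnorm(n)
  etiv <- rnorm(n, 1500, 120) * 1000
  ctx_gray <- 0.32 * etiv * (1 - 0.0030 * (age - 18)) + rnorm(n, 0, 8000)
  ctx_white <- 0.30 * etiv * (1 - 0.0012 * (age - 18)) + rnorm(n, 0, 8000)
  sub_gray <- 0.040 * etiv * (1 - 0.0020 * (age - 18)) + rnorm(n, 0, 1500)
  # cognition: working memory degrades with frontoparietal stiffness,
  # cognitive flexibility with global stiffness
  fp_stiff <- pmin(pmax(stiff + config$regional_stiffness_offsets[
    "frontoparietal"], 0.02), 0.98)
  ospan <- round(pmin(pmax(62 - 35 * (fp_stiff - 0.5) -
                             0.15 * (age - mid_age) + rnorm(n, 0, 6), 5), 75))
  wcst_err <- round(pmin(pmax(18 + 30 * (stiff - 0.5) +
                                0.15 * (age - mid_age) + rnorm(n, 0, 5),
                              0), 60))
  data.frame(
    subject_id = sprintf("s%03d", seq_len(n)),
    age_years = age, gender = gender, bmi = bmi,
    resting_hr_bpm = resting_hr, activity_score = activity_score,
    systolic_mmhg = systolic, diastolic_mmhg = diastolic,
    pulse_pressure_mmhg = systolic - diastolic,
    etiv_mm3 = etiv, cortical_gray_mm3 = ctx_gray,
    cortical_white_mm3 = ctx_white, subcortical_gray_mm3 = sub_gray,
    ospan_score = ospan, wcst_errors = wcst_err,
    true_stiffness = stiff,
    true_compliance = kernel_compliance(stiff, config$k_max),
    true_pulse_pressure_au = pp,
    stringsAsFactors = FALSE)
}

# Channel-level stiffness for one subject: subject stiffness plus the
# regional offsets, clamped to [0.02, 0.98].
channel_stiffness <- function(config, subj_stiffness, geometry) {
  off <- config$regional_stiffness_offsets[geometry$region_group]
  off[is.na(off)] <- 0
  s <- pmin(pmax(subj_stiffness + as.numeric(off), 0.02), 0.98)
  names(s) <- geometry$channel_id
  s
}

# Ground truth (beats, artifacts, ectopics) for one cohort row.
subject_truth <- function(config, row, geometry) {
  beats <- simulate_beat_times(config)
  art <- list()
  n_art <- rbinom(1, max(1, round(config$duration_s / 60)),
                  min(1, config$artifact_rate_per_min))
  if (n_art > 0) {
    starts <- sort(runif(n_art, 10, config$duration_s - 10 -
                           config$artifact_duration_s))
    art <- lapply(starts, function(s) c(s, s + config$artifact_duration_s))
  }
  ect <- numeric(0)
  n_ect <- rbinom(1, max(1, round(config$duration_s / 60)),
                  min(1, config$ectopic_rate_per_min))
  if (n_ect > 0 && length(beats) > 4) {
    host <- sort(sample(seq_len(length(beats) - 1), n_ect))
    ect <- beats[host] + 0.25
  }
  ground_truth(row$subject_id, beats,
               channel_stiffness(config, row$true_stiffness, geometry),
               pulse_pressure_au = row$true_pulse_pressure_au,
               noise_sd_au = config$noise_sd_au,
               artifact_windows_s = art, ectopic_times_s = ect)
}

#' Simulate one subject's recordings
#'
#' @param config A `sim_config`.
#' @param row One row of the cohort table (see [simulate_cohort()]).
#' @param geometry Montage geometry shared across the cohort.
#' @return List with `ekg` ([ekg_trace()]), `optical`
#'   ([optical_recording()]), `truth` ([ground_truth()]) and `geometry`.
#' @export
simulate_subject <- function(config, row,
                             geometry = make_montage(config$n_channels)) {
  truth <- subject_truth(config, row, geometry)
  list(ekg = simulate_ekg(config, truth),
       optical = simulate_optical(config, truth, geometry),
       truth = truth, geometry = geometry)
}

#' Simulate a full synthetic cohort
#'
#' Draws covariates and ground-truth stiffness for every subject (ages
#' spread evenly across six decades; stiffness increasing with age and
#' decreasing with the physical-activity score at the configured slopes)
#' and, optionally, the per-subject EKG and optical recordings.
#' Everything is reproducible from `config$seed`.
#'
#' @param config A `sim_config`.
#' @param recordings If `TRUE` (default) also simulate and return the
#'   per-subject recordings; set `FALSE` for covariates-only cohorts
#'   (cheap, e.g. for statistical simulations).
#' @return A list of class `sim_cohort`: `cohort` (data.frame with
#'   covariates and ground-truth columns), `geometry`, `recordings`
#'   (list or `NULL`), `config`.
#' @export
simulate_cohort <- function(config = sim_config(), recordings = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  geometry <- make_montage(config$n_channels)
  cohort <- cohort_covariates(config)
  recs <- NULL
  if (recordings) {
    recs <- lapply(seq_len(nrow(cohort)), function(i) {
      simulate_subject(config, cohort[i, ], geometry)
    })
    names(recs) <- cohort$subject_id
  }
  structure(list(cohort = cohort, geometry = geometry, recordings = recs,
                 config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d subjects, %d channels, %g s @ %g Hz%s\n",
              nrow(x$cohort), nrow(x$geometry), x$config$duration_s,
              x$config$fs_optical_hz,
              if (is.null(x$recordings)) " (covariates only)" else ""))
  invisible(x)
}
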