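# Synthetic signal generators: EKG traces with a QRS-like template at
# each ground-truth beat time, and multichannel optical recordings
# carrying a stiffness-controlled pulse kernel at each beat.

#' Diastolic decay shape of the pulse kernel
#'
#' On the normalized interval u in \[0, 1\] the decay is
#' `d(u) = (exp(-k u) - exp(-k)) / (1 - exp(-k))` for rate `k != 0` and
#' the straight line `1 - u` at `k = 0`.  Positive `k` gives a convex
#' fast drop (stiff vessel), negative `k` a sustained concave decay
#' (compliant vessel); `d(0) = 1`, `d(1) = 0` always.
#'
#' @param u Normalized time in \[0, 1\].
#' @param k Decay rate.
#' @return Decay values in \[0, 1\].
#' @export
diastolic_decay <- function(u, k) {
  if (abs(k) < 1e-8) return(1 - u)
  (exp(-k * u) - exp(-k)) / (1 - exp(-k))
}

#' Map stiffness to the kernel decay rate
#'
#' `k = k_max * (2 s - 1)`: stiffness 0.5 is the straight-line neutral
#' point, 1 the stiffest (fast convex decay), 0 the most compliant.
#'
#' @param stiffness Stiffness in \[0, 1\].
#' @param k_max Maximum absolute rate (default 6).
#' @return Decay rate(s).
#' @export
stiffness_to_k <- function(stiffness, k_max = 6) k_max * (2 * stiffness - 1)

#' Ground-truth arterial compliance of a kernel
#'
#' Closed form of the normalized area under [diastolic_decay()] minus
#' 0.5: `1/k - exp(-k)/(1 - exp(-k)) - 0.5`, and 0 at `k = 0`.  This is
#' the value the processing pipeline should recover from a noiseless
#' recording.
#'
#' @param stiffness Stiffness in \[0, 1\] (vectorized).
#' @param k_max Maximum absolute decay rate.
#' @return Compliance value(s) in (-0.5, 0.5).
#' @export
kernel_compliance <- function(stiffness, k_max = 6) {
  k <- stiffness_to_k(stiffness, k_max)
  ifelse(abs(k) < 1e-8, 0, 1 / k - exp(-k) / (1 - exp(-k)) - 0.5)
}

#' Evaluate the pulse kernel
#'
#' Unit-amplitude pulse shape on post-R time: zero until
#' `rise_start_ms`, a smooth half-cosine upstroke peaking at
#' `systole_ms`, then the stiffness-controlled diastolic decay reaching
#' zero at `diastole_ms`, and zero afterwards.
#'
#' @param t_ms Post-R times in ms (vectorized).
#' @param stiffness Stiffness in \[0, 1\].
#' @param config A `sim_config` (supplies the timing and `k_max`).
#' @return Kernel values in \[0, 1\].
#' @export
pulse_kernel <- function(t_ms, stiffness, config = sim_config()) {
  k <- stiffness_to_k(stiffness, config$k_max)
  y <- numeric(length(t_ms))
  r0 <- config$rise_start_ms; s0 <- config$systole_ms; d0 <- config$diastole_ms
  i_rise <- t_ms >= r0 & t_ms <= s0
  y[i_rise] <- 0.5 * (1 - cos(pi * (t_ms[i_rise] - r0) / (s0 - r0)))
  i_dec <- t_ms > s0 & t_ms < d0
  y[i_dec] <- diastolic_decay((t_ms[i_dec] - s0) / (d0 - s0), k)
  y
}

#' Simulate a one-lead EKG trace
#'
#' Places a QRS-like template (a narrow positive Gaussian with small
#' negative side lobes) at every ground-truth beat time, plus baseline
#' wander, respiratory modulation, white noise, and smaller templates at
#' any injected ectopic times.  The template peak coincides with the
#' beat time by construction.
#'
#' @param config A `sim_config`.
#' @param truth A `ground_truth` whose beat times lie inside the
#'   recording span.
#' @return An [ekg_trace()] with attribute `truth`.
#' @export
simulate_ekg <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  if (any(truth$beat_times_s < 0 | truth$beat_times_s > config$duration_s)) {
    stop("beat times fall outside the recording span")
  }
  fs <- config$fs_ekg_hz
  n <- floor(config$duration_s * fs) + 1
  t <- (seq_len(n) - 1) / fs
  v <- numeric(n)
  add_template <- function(v, at, amp) {
    i0 <- max(1L, floor((at - 0.06) * fs) + 1)
    i1 <- min(n, ceiling((at + 0.06) * fs) + 1)
    dt <- t[i0:i1] - at
    v[i0:i1] <- v[i0:i1] + amp * (exp(-(dt / 0.008)^2 / 2) -
                                    0.15 * exp(-((dt - 0.025) / 0.01)^2 / 2) -
                                    0.15 * exp(-((dt + 0.025) / 0.01)^2 / 2))
    v
  }
  for (b in truth$beat_times_s) v <- add_template(v, b, 1)
  for (b in truth$ectopic_times_s) v <- add_template(v, b, 0.7)
  wander <- 0.1 * sin(2 * pi * 0.25 * t + runif(1, 0, 2 * pi)) +
    0.05 * sin(2 * pi * 0.32 * t + runif(1, 0, 2 * pi))
  v <- v + wander
  if (config$ekg_noise_sd > 0) v <- v + rnorm(n, sd = config$ekg_noise_sd)
  out <- ekg_trace(v, fs, subject_id = truth$subject_id)
  attr(out, "truth") <- truth
  out
}

#' Simulate a multichannel optical recording
#'
#' Each channel carries, at every ground-truth beat time, a pulse kernel
#' whose diastolic shape is set by the channel's stiffness and whose
#' amplitude (in percent of the channel's mean intensity) is the
#' subject's pulse pressure, on top of the channel's mean intensity,
#' white noise, and any declared motion artifacts (a boxcar baseline
#' step plus high-amplitude spikes inside each artifact window).
#'
#' @param config A `sim_config`.
#' @param truth A `ground_truth` with one stiffness per channel.
#' @param geometry A `channel_geometry` naming the channels (default a
#'   fresh [make_montage()]).
#' @return An [optical_recording()] in `"au"` units with attribute
#'   `truth`; two equal halves of the recording are labelled blocks 1
#'   and 2.
#' @export
simulate_optical <- function(config, truth,
                             geometry = make_montage(config$n_channels)) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  nc <- length(truth$stiffness)
  if (nc != nrow(geometry)) stop("one stiffness value per channel required")
  fs <- config$fs_optical_hz
  n <- floor(config$duration_s * fs) + 1
  t <- (seq_len(n) - 1) / fs
  i0 <- config$mean_intensity_au
  k_vec <- stiffness_to_k(truth$stiffness, config$k_max)
  ac <- matrix(0, nc, n)
  r0 <- config$rise_start_ms / 1000
  d0 <- config$diastole_ms / 1000
  for (b in c(truth$beat_times_s, truth$ectopic_times_s)) {
    j0 <- max(1L, floor((b + r0) * fs))
    j1 <- min(n, ceiling((b + d0) * fs) + 1)
    if (j1 <= j0) next
    dt_ms <- (t[j0:j1] - b) * 1000
    for (c_i in seq_len(nc)) {
      ac[c_i, j0:j1] <- ac[c_i, j0:j1] +
        pulse_kernel(dt_ms, truth$stiffness[c_i], config)
    }
  }
  ac <- i0 * (1 + truth$pulse_pressure_au / 100 * ac)
  if (truth$noise_sd_au > 0) {
    ac <- ac + i0 / 100 * matrix(rnorm(nc * n, sd = truth$noise_sd_au), nc, n)
  }
  for (w in truth$artifact_windows_s) {
    j <- which(t >= w[1] & t <= w[2])
    if (!length(j)) next
    ac[, j] <- ac[, j] + i0 * 0.05                   # baseline step
    spikes <- unique(c(j[seq(1, length(j), by = max(1, floor(fs / 4)))],
                       j[length(j)]))
    sgn <- rep_len(c(1, -1), length(spikes))
    ac[, spikes] <- ac[, spikes] + i0 * 0.10 * matrix(sgn, nc, length(spikes),
                                                      byrow = TRUE)
  }
  blocks <- data.frame(block_id = c(1L, 2L),
                       start_s = c(0, config$duration_s / 2),
                       end_s = c(config$duration_s / 2, config$duration_s))
  out <- optical_recording(ac, fs_hz = fs, channel_ids = geometry$channel_id,
                           subject_id = truth$subject_id, blocks = blocks,
                           geometry = geometry, units = "au")
  attr(out, "truth") <- truth
  out
}
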