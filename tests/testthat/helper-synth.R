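# Shared fixture builders for the test suite.  All fixtures are built in
# code under fixed seeds; nothing is read from disk.

# A small, fast configuration: 4 channels, short recording.
quick_config <- function(duration_s = 60, noise_sd_au = 0, n_channels = 4,
                         ...) {
  sim_config(n_subjects = 1, duration_s = duration_s,
             noise_sd_au = noise_sd_au, ekg_noise_sd = 0,
             n_channels = n_channels,
             regional_stiffness_offsets = c(frontoparietal = 0, visual = 0),
             ...)
}

# Ground truth with regular beats at the configured heart rate and a
# single stiffness for all channels.
quick_truth <- function(config, stiffness = 0.5, hr_bpm = 60,
                        pulse_pressure_au = 1, noise_sd_au = config$noise_sd_au,
                        ...) {
  beats <- seq(0.5, config$duration_s - 1.2, by = 60 / hr_bpm)
  ground_truth("test", beats,
               stiffness = setNames(rep(stiffness, config$n_channels),
                                    sprintf("ch%02d", seq_len(config$n_channels))),
               pulse_pressure_au = pulse_pressure_au,
               noise_sd_au = noise_sd_au, ...)
}

# Baselined pulse_waveform carrying the generator kernel on the native
# post-R grid.
kernel_waveform <- function(stiffness = 0.5, config = sim_config(),
                            span_ms = 1000, fs_hz = config$fs_optical_hz,
                            amplitude = 1) {
  grid <- seq(0, span_ms, by = 1000 / fs_hz)
  w <- pulse_waveform(amplitude * pulse_kernel(grid, stiffness, config), grid,
                      n_epochs = 200L, unit_id = "kernel")
  w$baselined <- TRUE
  w
}

# Normalized diastolic segment sampled from a decay function d(t) with
# d(0) = 1, d(1) = 0.
nd_from_fun <- function(d, n = 18) {
  t <- seq(0, 1, length.out = n)
  structure(list(t_norm = t, y_norm = d(t), qc_flags = character(0),
                 unit_id = "synthetic"),
            class = "normalized_diastole")
}

# Random monotone decay built as a convex mixture of a straight line and
# two exponential decays with rates drawn in [-6, 6]; always maps
# 1 -> 0 monotonically on [0, 1].
random_decay <- function() {
  w <- runif(3); w <- w / sum(w)
  k1 <- runif(1, -6, 6); k2 <- runif(1, -6, 6)
  function(t) {
    w[1] * (1 - t) + w[2] * diastolic_decay(t, k1) +
      w[3] * diastolic_decay(t, k2)
  }
}

# High-resolution trapezoid oracle for the compliance of a decay
# function (independent of the package's arterial_compliance path).
compliance_oracle <- function(d, n = 100001) {
  t <- seq(0, 1, length.out = n)
  y <- d(t)
  sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2) - 0.5
}
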