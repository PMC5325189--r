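test_that("normalization gives percent change about the channel mean", {
  fs <- 39.0625
  t <- seq(0, 60, by = 1 / fs)
  ac <- rbind(rep(1000, length(t)),
              1000 * (1 + 0.01 * sin(2 * pi * 1.2 * t)),
              5000 * (1 + 0.01 * sin(2 * pi * 1.2 * t)))
  rec <- normalize_channels(optical_recording(ac, fs))
  expect_equal(rec$units, "pct")
  expect_equal(max(abs(rec$ac[1, ])), 0)
  # 1% modulation becomes amplitude ~1 in percent units
  expect_equal(max(rec$ac[2, ]), 1, tolerance = 1e-3)
  # gain invariance: channels differing only by gain normalize identically
  expect_equal(rec$ac[2, ], rec$ac[3, ], tolerance = 1e-12)
})

test_that("channels with non-positive mean are dropped with a warning", {
  ac <- rbind(rep(1000, 100) + rnorm(100), rep(-5, 100))
  expect_warning(rec <- normalize_channels(optical_recording(ac, 39.0625)),
                 "non-positive")
  expect_equal(nrow(rec$ac), 1)
  expect_equal(rec$dropped_channels, "ch02")
})

test_that("optical band-pass separates drift, pulse and high frequencies", {
  fs <- 39.0625
  t <- seq(0, 120, by = 1 / fs)
  drift <- sin(2 * pi * 0.05 * t)
  pulse <- sin(2 * pi * 1.2 * t)
  hi <- sin(2 * pi * 10 * t)
  rec <- optical_recording(rbind(drift + pulse, hi, 0 * t), fs, units = "pct")
  out <- bandpass_optical(rec)
  # drift removed, pulse preserved on the mixed channel
  resid_drift <- out$ac[1, ] - pulse
  expect_lt(sd(out$ac[1, ] - pulse), 0.35 * sd(drift))  # pulse-band error
  # direct attenuation checks on pure tones
  rec2 <- bandpass_optical(optical_recording(rbind(drift, hi), fs,
                                             units = "pct"))
  expect_lt(sd(rec2$ac[1, ]), 0.1 * sd(drift))
  expect_lt(sd(rec2$ac[2, ]), 0.2 * sd(hi))
  # zero in, zero out
  expect_equal(max(abs(out$ac[3, ])), 0)
})

test_that("pass-band gain at 1.2 Hz is within 10% of unity", {
  fs <- 39.0625
  t <- seq(0, 120, by = 1 / fs)
  x <- sin(2 * pi * 1.2 * t)
  out <- bandpass_optical(optical_recording(rbind(x), fs, units = "pct"))
  expect_gt(sd(out$ac[1, ]) / sd(x), 0.9)
  expect_lt(sd(out$ac[1, ]) / sd(x), 1.1)
})

test_that("epoch averaging recovers a noiseless kernel to within 1% of peak", {
  cfg <- quick_config(duration_s = 180)
  truth <- quick_truth(cfg, stiffness = 0.3)
  set.seed(31)
  rec <- normalize_channels(simulate_optical(cfg, truth))
  beats <- beat_set(truth$beat_times_s)
  waves <- suppressWarnings(epoch_and_average(rec, beats))
  w <- waves[[1]]
  kern <- truth$pulse_pressure_au * pulse_kernel(w$time_ms, 0.3, cfg)
  kern <- kern - mean(kern)  # channel-mean removal offsets the epoch too
  expect_lt(max(abs(w$y - kern)), 0.01 * max(kern) + 0.005)
  expect_gt(cor(w$y, kern), 0.999)
})

test_that("averaging attenuates white noise roughly as 1/sqrt(n)", {
  cfg <- quick_config(duration_s = 360, noise_sd_au = 0.5)
  truth <- quick_truth(cfg, pulse_pressure_au = 1e-9)  # noise-only channels
  set.seed(33)
  rec <- normalize_channels(simulate_optical(cfg, truth))
  beats <- beat_set(truth$beat_times_s)
  waves <- epoch_and_average(rec, beats)
  n <- waves[[1]]$n_epochs
  expect_gte(n, 100)
  rms <- sd(waves[[1]]$y)
  expect_lt(rms, 3 * truth$noise_sd_au / sqrt(n))
  expect_gt(rms, truth$noise_sd_au / sqrt(n) / 2)
})

test_that("single-beat averaging flags the low-epoch waveform", {
  cfg <- quick_config(duration_s = 60)
  truth <- quick_truth(cfg)
  set.seed(35)
  rec <- normalize_channels(simulate_optical(cfg, truth))
  one <- beat_set(truth$beat_times_s[1])
  expect_warning(waves <- epoch_and_average(rec, one), "fewer than")
  expect_equal(waves[[1]]$n_epochs, 1L)
  expect_true("low_epochs" %in% waves[[1]]$flags)
})

test_that("epochs truncated by the next beat are excluded", {
  cfg <- quick_config(duration_s = 120)
  truth <- quick_truth(cfg, hr_bpm = 60)
  set.seed(37)
  rec <- normalize_channels(simulate_optical(cfg, truth))
  # insert an extra beat 0.7 s after beat 10: the epoch at beat 10 is now
  # truncated (interval < 1 s) and must not be averaged
  beats_plus <- beat_set(sort(c(truth$beat_times_s,
                                truth$beat_times_s[10] + 0.7)))
  w_ref <- suppressWarnings(epoch_and_average(rec, beat_set(truth$beat_times_s)))
  w_plus <- suppressWarnings(epoch_and_average(rec, beats_plus))
  # beat 10's epoch becomes truncated and drops out of the average
  expect_equal(w_plus[[1]]$n_epochs, w_ref[[1]]$n_epochs - 1L)
})

test_that("baselining zeroes the 128-256 ms window and is idempotent", {
  w <- kernel_waveform(0.4)
  w$y <- w$y + 3.7  # arbitrary offset
  b1 <- baseline_waveform(w)
  i <- b1$time_ms >= 128 & b1$time_ms <= 256
  expect_lt(abs(mean(b1$y[i])), 1e-9 * max(abs(b1$y)))
  b2 <- baseline_waveform(b1)
  expect_equal(b1$y, b2$y, tolerance = 1e-12)
  # constant waveform baselines to all zeros
  wc <- pulse_waveform(rep(4.2, length(w$time_ms)), w$time_ms)
  expect_equal(max(abs(baseline_waveform(wc)$y)), 0)
  # grid not covering the window errors
  ws <- pulse_waveform(1:5, seq(300, 700, length.out = 5))
  expect_error(baseline_waveform(ws), "baseline window")
})

test_that("artifact windows mask exactly the overlapping epochs", {
  cfg <- quick_config(duration_s = 240, noise_sd_au = 0.5, n_channels = 2)
  truth <- quick_truth(cfg, hr_bpm = 58)
  truth$artifact_windows_s <- list(c(100, 105))
  set.seed(41)
  rec <- normalize_channels(simulate_optical(cfg, truth))
  beats <- beat_set(truth$beat_times_s)
  keep <- reject_artifacts(rec, beats)
  ep <- attr(keep, "epochs")
  overlaps <- ep$time_s + 1 >= 100 & ep$time_s <= 105
  for (ch in seq_len(nrow(keep))) {
    expect_equal(which(!keep[ch, ]), which(overlaps))
  }
})

test_that("a clean recording yields an empty artifact mask", {
  cfg <- quick_config(duration_s = 240, noise_sd_au = 0.5, n_channels = 2)
  truth <- quick_truth(cfg)
  set.seed(43)
  rec <- normalize_channels(simulate_optical(cfg, truth))
  keep <- reject_artifacts(rec, beat_set(truth$beat_times_s))
  expect_true(all(keep))
  expect_equal(nrow(attr(keep, "log")), 0)
})

test_that("an all-artifact channel is signalled unusable", {
  cfg <- quick_config(duration_s = 120, noise_sd_au = 0.5, n_channels = 2)
  truth <- quick_truth(cfg)
  truth$artifact_windows_s <- list(c(0, 120))
  set.seed(45)
  rec <- normalize_channels(simulate_optical(cfg, truth))
  expect_warning(keep <- reject_artifacts(rec, beat_set(truth$beat_times_s)),
                 "unusable")
  expect_true(all(rowSums(keep) == 0))
})
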