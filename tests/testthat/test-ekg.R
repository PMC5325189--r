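test_that("EKG band-pass rejects stop bands and preserves the pass band", {
  fs <- 1000
  t <- seq(0, 60, by = 1 / fs)
  tr_slow <- ekg_trace(sin(2 * pi * 0.1 * t), fs)
  out <- bandpass_ekg(tr_slow)
  expect_lt(sd(out$v), 0.05 * sd(tr_slow$v))
  expect_lt(abs(mean(out$v)), 1e-6)

  tr_mid <- ekg_trace(sin(2 * pi * 10 * t), fs)
  expect_gt(sd(bandpass_ekg(tr_mid)$v), 0.9 * sd(tr_mid$v))
  expect_lt(sd(bandpass_ekg(tr_mid)$v), 1.1 * sd(tr_mid$v))
})

test_that("filtered white noise loses >= 20 dB of power above 45 Hz", {
  set.seed(11)
  fs <- 1000
  tr <- ekg_trace(rnorm(60 * fs), fs)
  out <- bandpass_ekg(tr)
  sp <- spec.pgram(ts(out$v, frequency = fs), plot = FALSE, taper = 0)
  p_pass <- mean(sp$spec[sp$freq > 8 & sp$freq < 12])
  p_stop <- mean(sp$spec[sp$freq > 45])
  expect_gt(10 * log10(p_pass / p_stop), 20)
})

test_that("R waves in a clean synthetic EKG are all recovered", {
  cfg <- quick_config(duration_s = 60)
  truth <- quick_truth(cfg, hr_bpm = 60)
  set.seed(21)
  trace <- simulate_ekg(cfg, truth)
  beats <- detect_rwaves(bandpass_ekg(trace))
  sc <- score_detection(beats, truth$beat_times_s, tol_s = 0.01)
  expect_equal(sc$fn, 0)
  expect_equal(sc$fp, 0)
  expect_equal(length(beats$r_times_s), length(truth$beat_times_s))
  # bookkeeping: every candidate is either accepted or carries one reason
  expect_equal(beats$n_candidates,
               length(beats$r_times_s) + nrow(beats$rejected))
})

test_that("noiseless template argmax peaks sit at the injected beat times", {
  cfg <- quick_config(duration_s = 60)
  cfg$ekg_noise_sd <- 0
  for (hr in c(60, 75)) {
    truth <- quick_truth(cfg, hr_bpm = hr)
    set.seed(3)
    trace <- simulate_ekg(cfg, truth)
    trace$v <- trace$v - stats::runmed(trace$v, 501)  # strip wander
    # count and place threshold crossings of the noiseless trace
    pk <- which(diff(sign(diff(trace$v))) == -2) + 1
    pk <- pk[trace$v[pk] > 0.5]
    expect_equal(length(pk), length(truth$beat_times_s))
    expect_lt(max(abs((pk - 1) / cfg$fs_ekg_hz - truth$beat_times_s)), 0.002)
  }
})

test_that("detection is invariant to positive rescaling of the trace", {
  cfg <- quick_config(duration_s = 60)
  truth <- quick_truth(cfg)
  set.seed(5)
  trace <- simulate_ekg(cfg, truth)
  b1 <- detect_rwaves(bandpass_ekg(trace))
  trace$v <- trace$v * 5
  b2 <- detect_rwaves(bandpass_ekg(trace))
  expect_identical(b1$r_times_s, b2$r_times_s)
})

test_that("ectopic beats are rejected with a reason code", {
  cfg <- quick_config(duration_s = 60)
  truth <- quick_truth(cfg)
  # ectopic 250 ms after a true beat: outside the refractory window but
  # inside the short-interval band, so the interbeat filter removes it
  truth$ectopic_times_s <- truth$beat_times_s[10] + 0.25
  set.seed(7)
  beats <- detect_rwaves(bandpass_ekg(simulate_ekg(cfg, truth)))
  hit <- abs(beats$rejected$time_s - truth$ectopic_times_s) < 0.02
  expect_true(any(hit))
  expect_equal(beats$rejected$reason[hit], "interbeat_interval")
  expect_false(any(abs(beats$r_times_s - truth$ectopic_times_s) < 0.02))

  # ectopic 150 ms after a true beat falls inside the refractory window
  truth$ectopic_times_s <- truth$beat_times_s[10] + 0.15
  set.seed(7)
  beats2 <- detect_rwaves(bandpass_ekg(simulate_ekg(cfg, truth)))
  hit2 <- abs(beats2$rejected$time_s - truth$ectopic_times_s) < 0.02
  expect_true(any(hit2))
  expect_false(any(abs(beats2$r_times_s - truth$ectopic_times_s) < 0.02))
})

test_that("an all-zero trace raises the no-beats condition", {
  tr <- ekg_trace(rep(0, 1000), 1000)
  tr$filtered <- TRUE
  expect_error(detect_rwaves(tr), class = "cerepulse_no_beats")
})

test_that("manual overrides apply deterministically and re-validate", {
  cfg <- quick_config(duration_s = 60)
  truth <- quick_truth(cfg)
  set.seed(9)
  beats <- detect_rwaves(bandpass_ekg(simulate_ekg(cfg, truth)))
  n0 <- length(beats$r_times_s)

  dropped <- override_beats(beats, drop_times_s = beats$r_times_s[5])
  expect_equal(length(dropped$r_times_s), n0 - 1)
  expect_true("manual" %in% dropped$rejected$reason)

  # adding an existing time is idempotent
  same <- override_beats(beats, add_times_s = beats$r_times_s[5])
  expect_equal(length(same$r_times_s), n0)
  expect_false(any(duplicated(same$r_times_s)))

  # an edit creating a 0.1 s interval violates the band
  expect_error(override_beats(beats,
                              add_times_s = beats$r_times_s[5] + 0.1),
               "interbeat interval")
})
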