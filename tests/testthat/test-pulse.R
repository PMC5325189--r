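test_that("pulse amplitude is the in-window mean and is linear", {
  set.seed(51)
  grid <- seq(0, 1000, by = 25.6)
  y <- rnorm(length(grid))
  w <- pulse_waveform(y, grid)
  w$baselined <- TRUE
  # brute-force oracle: direct summation over in-window samples
  i <- grid >= 384 & grid <= 538
  expect_equal(pulse_amplitude(w), sum(y[i]) / sum(i), tolerance = 1e-12)
  w2 <- w; w2$y <- 2 * w$y
  expect_equal(pulse_amplitude(w2), 2 * pulse_amplitude(w), tolerance = 1e-12)
  w0 <- w; w0$y <- 0 * w$y
  expect_equal(pulse_amplitude(w0), 0)
})

test_that("peak location finds the injected systole and handles edge cases", {
  w <- kernel_waveform(0.5)
  pk <- locate_peaks(w)
  expect_lt(abs(pk$systole_time_ms - 450), 25.6 + 1e-9)
  # monotone decay after the peak: diastole at the last searched sample
  expect_equal(pk$diastole_time_ms, max(w$time_ms[w$time_ms <= 900]))
  # flat waveform is flagged degenerate, not an error
  wf <- pulse_waveform(rep(0, length(w$time_ms)), w$time_ms)
  pkf <- locate_peaks(wf)
  expect_true("flat_waveform" %in% pkf$qc_flags)
  expect_true(is.na(pkf$systole_time_ms))
})

test_that("diastole normalization pins endpoints and rejects inversions", {
  w <- kernel_waveform(0.3)
  nd <- normalize_diastole(w)
  expect_equal(nd$y_norm[1], 1)
  expect_equal(nd$y_norm[length(nd$y_norm)], 0)
  expect_true(all(diff(nd$t_norm) > 0))
  expect_equal(range(nd$t_norm), c(0, 1))
  # inverted anchors (systolic value below diastolic) error
  pk_bad <- list(systole_time_ms = 450, systole_value = 0,
                 diastole_time_ms = 800, diastole_value = 1)
  expect_error(normalize_diastole(w, pk_bad), "inverted")
})

test_that("compliance hits the analytic endpoints", {
  # straight oblique decay -> 0 (trapezoid is exact for a line)
  nd_lin <- nd_from_fun(function(t) 1 - t, n = 101)
  expect_equal(as.numeric(arterial_compliance(nd_lin)), 0, tolerance = 1e-12)
  # flat at systolic level for the whole diastole -> 0.5 in the dense limit
  n <- 10001
  t <- seq(0, 1, length.out = n)
  nd_flat <- structure(list(t_norm = t, y_norm = c(rep(1, n - 1), 0),
                            qc_flags = character(0), unit_id = "flat"),
                       class = "normalized_diastole")
  expect_equal(as.numeric(arterial_compliance(nd_flat)), 0.5,
               tolerance = 1e-3)
})

test_that("compliance of an exponential decay matches the numeric oracle", {
  d3 <- function(t) diastolic_decay(t, 3)
  oracle <- compliance_oracle(d3)
  expect_equal(oracle, -0.219, tolerance = 1e-3)
  nd <- nd_from_fun(d3, n = 1000)
  expect_equal(as.numeric(arterial_compliance(nd)), oracle, tolerance = 1e-3)
  # closed-form ground truth used by the generator agrees too
  expect_equal(kernel_compliance(0.75, k_max = 6), oracle, tolerance = 1e-6)
})

test_that("compliance is invariant to affine amplitude and time dilation", {
  set.seed(53)
  for (rep in 1:25) {
    d <- random_decay()
    grid <- seq(0, 1000, by = 25.6)
    y <- numeric(length(grid))
    ris <- grid >= 300 & grid <= 450
    y[ris] <- 0.5 * (1 - cos(pi * (grid[ris] - 300) / 150))
    dec <- grid > 450 & grid < 900
    y[dec] <- d((grid[dec] - 450) / 450)
    w <- pulse_waveform(y, grid); w$baselined <- TRUE
    base <- as.numeric(arterial_compliance(normalize_diastole(w)))
    # positive affine amplitude transform
    a <- runif(1, 0.1, 10); b <- runif(1, -5, 5)
    w2 <- pulse_waveform(a * y + b, grid); w2$baselined <- TRUE
    expect_equal(as.numeric(arterial_compliance(normalize_diastole(w2))),
                 base, tolerance = 1e-9)
    # uniform time dilation: same samples on a stretched clock, with the
    # peak anchors stretched accordingly
    s <- runif(1, 0.5, 2)
    pk <- locate_peaks(w)
    w3 <- pulse_waveform(y, grid * s)
    w3$baselined <- TRUE
    pk3 <- pk
    pk3$systole_time_ms <- pk$systole_time_ms * s
    pk3$diastole_time_ms <- pk$diastole_time_ms * s
    expect_equal(as.numeric(arterial_compliance(normalize_diastole(w3, pk3))),
                 base, tolerance = 1e-9)
  }
})

test_that("compliance is monotone under pointwise increase of the decay", {
  set.seed(55)
  for (rep in 1:10) {
    d <- random_decay()
    nd <- nd_from_fun(d, n = 30)
    c0 <- as.numeric(arterial_compliance(nd))
    lift <- nd
    bump <- runif(28, 0, 0.05)
    lift$y_norm <- pmin(lift$y_norm + c(0, bump, 0), 1)
    expect_gte(as.numeric(arterial_compliance(lift)), c0)
  }
})

test_that("amplitude and compliance are decoupled", {
  w <- kernel_waveform(0.35, amplitude = 1)
  idx1 <- indices_per_unit(list(a = w))
  w2 <- kernel_waveform(0.35, amplitude = 3.1)
  idx2 <- indices_per_unit(list(a = w2))
  expect_equal(idx2$amplitude_pct, 3.1 * idx1$amplitude_pct,
               tolerance = 1e-9)
  expect_equal(idx2$compliance, idx1$compliance, tolerance = 1e-9)
})

test_that("per-unit indices aggregate as unweighted ROI means", {
  waves <- list(u1 = kernel_waveform(0.3), u2 = kernel_waveform(0.7))
  waves$u1$unit_id <- "u1"; waves$u2$unit_id <- "u2"
  idx <- indices_per_unit(waves)
  agg <- aggregate_indices(idx, c("u1", "u2"))
  expect_equal(agg, mean(idx$compliance), tolerance = 1e-12)
  expect_equal(aggregate_indices(idx, "u2"),
               idx$compliance[idx$unit_id == "u2"])
  expect_error(aggregate_indices(idx, character(0)), "empty ROI")
})

test_that("out-of-range normalized samples are flagged but integrated", {
  nd <- nd_from_fun(function(t) 1 - t, n = 50)
  nd$y_norm[25] <- 1.2
  nd$qc_flags <- "out_of_range"
  comp <- arterial_compliance(nd)
  expect_true("out_of_range" %in% attr(comp, "qc_flags"))
  expect_gt(as.numeric(comp), 0)
})
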