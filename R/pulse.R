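# The two cerebrovascular indices derived from the averaged, baselined
# pulse waveform:
#
#   * pulse amplitude  - mean percent-change intensity over the systolic
#     window (384-538 ms post-R), a proxy for cerebral pulse pressure;
#   * arterial compliance - the area under the diastolic limb after
#     normalizing time and amplitude to the unit square, minus 0.5.
#
# Compliance compares the diastolic decay against a hypothetical straight
# oblique line from the systolic peak to the diastolic trough: a linear
# decay scores 0, a decay that holds near the systolic level for the
# whole diastole approaches +0.5 (elastic, sustained recoil), and a fast
# convex drop approaches -0.5 (stiff).  It is by construction invariant
# to amplitude scaling and time dilation, so it decouples from pulse
# amplitude.

#' Pulse amplitude of a baselined waveform
#'
#' Mean of the waveform over the systolic window (default 384--538 ms
#' post-R, an interval containing the systolic peak in adults across
#' brain regions).  Linear in the waveform.
#'
#' @param w A baselined `pulse_waveform`.
#' @param window_ms Systolic window in ms.
#' @return Mean percent-change intensity in the window.
#' @export
pulse_amplitude <- function(w, window_ms = c(384, 538)) {
  stopifnot(inherits(w, "pulse_waveform"))
  i <- which(w$time_ms >= window_ms[1] & w$time_ms <= window_ms[2])
  if (!length(i)) stop("waveform grid does not cover the amplitude window")
  mean(w$y[i])
}

#' Locate the systolic peak and the diastolic reference
#'
#' The systolic peak is the maximum of the waveform inside the systolic
#' window; the diastolic reference is the minimum between the systolic
#' peak and a search cap (default 900 ms post-R, before the next beat's
#' upstroke can intrude).  Ties break to the earliest sample.  A flat
#' search region (no unique peak) yields `NA` times and the
#' `"flat_waveform"` QC flag rather than an error.
#'
#' @param w A baselined `pulse_waveform`.
#' @param systole_window_ms Window searched for the systolic maximum.
#' @param diastole_cap_ms Latest time searched for the diastolic minimum.
#' @return A list with `systole_time_ms`, `systole_value`,
#'   `diastole_time_ms`, `diastole_value`, `qc_flags`.
#' @export
locate_peaks <- function(w, systole_window_ms = c(384, 538),
                         diastole_cap_ms = 900) {
  stopifnot(inherits(w, "pulse_waveform"))
  i_sys <- which(w$time_ms >= systole_window_ms[1] &
                   w$time_ms <= systole_window_ms[2])
  if (!length(i_sys)) stop("waveform grid does not cover the systolic window")
  ys <- w$y[i_sys]
  if (any(!is.finite(ys))) stop("non-finite values in the systolic window")
  if (diff(range(ys)) == 0 && diff(range(w$y, finite = TRUE)) == 0) {
    return(list(systole_time_ms = NA_real_, systole_value = NA_real_,
                diastole_time_ms = NA_real_, diastole_value = NA_real_,
                qc_flags = "flat_waveform"))
  }
  i_peak <- i_sys[which.max(ys)]
  i_dia <- which(w$time_ms > w$time_ms[i_peak] & w$time_ms <= diastole_cap_ms)
  if (!length(i_dia)) stop("no samples between the systolic peak and the cap")
  yd <- w$y[i_dia]
  if (any(!is.finite(yd))) stop("non-finite values in the diastolic search region")
  i_min <- i_dia[which.min(yd)]
  list(systole_time_ms = w$time_ms[i_peak], systole_value = w$y[i_peak],
       diastole_time_ms = w$time_ms[i_min], diastole_value = w$y[i_min],
       qc_flags = character(0))
}

#' Normalize the diastolic limb to the unit square
#'
#' Affinely maps time so the systolic peak is at 0 and the diastolic
#' reference at 1, and amplitude so the systolic peak is 1 and the
#' diastolic reference 0.  Samples escaping [0, 1] (noise overshoot) are
#' kept as-is but flagged `"out_of_range"`.
#'
#' @param w A baselined `pulse_waveform`.
#' @param peaks Output of [locate_peaks()] for `w`.
#' @return An object of class `normalized_diastole` with fields `t_norm`,
#'   `y_norm`, `qc_flags`, `unit_id`.
#' @export
normalize_diastole <- function(w, peaks = locate_peaks(w)) {
  stopifnot(inherits(w, "pulse_waveform"))
  if (!is.finite(peaks$systole_time_ms)) {
    stop("cannot normalize a flat waveform (no unique systolic peak)")
  }
  if (peaks$systole_value <= peaks$diastole_value) {
    stop("inverted waveform: systolic value must exceed the diastolic value")
  }
  i <- which(w$time_ms >= peaks$systole_time_ms &
               w$time_ms <= peaks$diastole_time_ms)
  t_norm <- (w$time_ms[i] - peaks$systole_time_ms) /
    (peaks$diastole_time_ms - peaks$systole_time_ms)
  y_norm <- (w$y[i] - peaks$diastole_value) /
    (peaks$systole_value - peaks$diastole_value)
  qc <- character(0)
  if (any(y_norm < -1e-9 | y_norm > 1 + 1e-9)) qc <- "out_of_range"
  structure(list(t_norm = t_norm, y_norm = y_norm, qc_flags = qc,
                 unit_id = w$unit_id),
            class = "normalized_diastole")
}

#' Arterial compliance of a normalized diastolic limb
#'
#' Trapezoidal area under `y_norm` over `t_norm` in [0, 1], minus 0.5
#' (the area of the straight oblique line joining the systolic peak to
#' the diastolic trough).  For `y_norm` within [0, 1] the result is
#' bounded by ±0.5; out-of-range samples are integrated as-is and
#' reported through the object's QC flag.
#'
#' @param nd A `normalized_diastole` with at least 3 samples.
#' @return Dimensionless compliance, with attribute `qc_flags`.
#' @export
arterial_compliance <- function(nd) {
  stopifnot(inherits(nd, "normalized_diastole"))
  if (length(nd$t_norm) < 3) {
    stop("need at least 3 samples between the systolic and diastolic peaks")
  }
  structure(pracma::trapz(nd$t_norm, nd$y_norm) - 0.5,
            qc_flags = nd$qc_flags)
}

#' Refine a waveform grid by cubic-spline oversampling
#'
#' The native 25.6 ms sampling undersamples the systolic crest: the
#' sample maximum can sit a quarter of a beat-width away from the true
#' peak, which biases the compliance estimate by including part of the
#' crest in (or clipping it from) the normalized diastolic segment.
#' Interpolating the averaged waveform with a cubic spline before peak
#' location recovers the crest to sub-sample precision; the averaged
#' waveform is smooth enough (noise is already beaten down by epoch
#' averaging) for spline interpolation to be accurate.
#'
#' @param w A `pulse_waveform`.
#' @param factor Oversampling factor (default 10).
#' @return A `pulse_waveform` on a `factor`-times finer grid.
#' @export
oversample_waveform <- function(w, factor = 10) {
  stopifnot(inherits(w, "pulse_waveform"))
  if (factor <= 1) return(w)
  f <- stats::splinefun(w$time_ms, w$y, method = "fmm")
  tg <- seq(min(w$time_ms), max(w$time_ms),
            by = diff(w$time_ms[1:2]) / factor)
  out <- pulse_waveform(f(tg), tg, n_epochs = w$n_epochs,
                        unit_id = w$unit_id,
                        baseline_window_ms = w$baseline_window_ms,
                        flags = w$flags)
  out$baselined <- w$baselined
  out
}

#' Per-unit pulse indices
#'
#' Computes pulse amplitude and arterial compliance for every waveform,
#' with peak annotations and QC flags.  Amplitude is the mean of the
#' native in-window samples; peak location, diastole normalization and
#' the compliance integral run on a spline-oversampled copy of the
#' waveform (see [oversample_waveform()]) so the systolic anchor is not
#' quantized to the native grid.  Degenerate units (flat waveform,
#' inverted diastole, too few samples) receive `NA` indices and a flag
#' instead of aborting the batch.
#'
#' @param waveforms Named list of baselined `pulse_waveform` objects.
#' @param amplitude_window_ms Systolic window for [pulse_amplitude()].
#' @param diastole_cap_ms Search cap for [locate_peaks()].
#' @param oversample Spline oversampling factor for the peak/compliance
#'   path (default 10; 1 disables).
#' @return A data.frame with one row per unit: `unit_id`,
#'   `amplitude_pct`, `compliance`, `systole_time_ms`, `diastole_time_ms`,
#'   `n_epochs`, `qc_flags` (semicolon-joined).
#' @export
indices_per_unit <- function(waveforms, amplitude_window_ms = c(384, 538),
                             diastole_cap_ms = 900, oversample = 10) {
  rows <- lapply(waveforms, function(w) {
    stopifnot(inherits(w, "pulse_waveform"))
    flags <- w$flags
    amp <- comp <- ts <- td <- NA_real_
    ok <- all(is.finite(w$y))
    if (!ok) flags <- union(flags, "non_finite")
    if (ok) {
      amp <- pulse_amplitude(w, amplitude_window_ms)
      wf <- oversample_waveform(w, oversample)
      pk <- locate_peaks(wf, amplitude_window_ms, diastole_cap_ms)
      flags <- union(flags, pk$qc_flags)
      if (is.finite(pk$systole_time_ms) &&
          pk$systole_value > pk$diastole_value) {
        ts <- pk$systole_time_ms; td <- pk$diastole_time_ms
        nd <- normalize_diastole(wf, pk)
        flags <- union(flags, nd$qc_flags)
        if (length(nd$t_norm) >= 3) {
          comp <- as.numeric(arterial_compliance(nd))
        } else {
          flags <- union(flags, "short_segment")
        }
      } else if (is.finite(pk$systole_time_ms)) {
        flags <- union(flags, "inverted_waveform")
      }
    }
    data.frame(unit_id = w$unit_id, amplitude_pct = amp, compliance = comp,
               systole_time_ms = ts, diastole_time_ms = td,
               n_epochs = w$n_epochs,
               qc_flags = paste(flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate per-unit indices over a region of interest
#'
#' Unweighted mean of a per-unit index over the units inside an ROI,
#' optionally excluding QC-flagged units.
#'
#' @param indices Output of [indices_per_unit()].
#' @param unit_ids Units to aggregate (default all).
#' @param value Column to aggregate, `"compliance"` or `"amplitude_pct"`.
#' @param exclude_flagged If `TRUE`, drop units with any QC flag before
#'   averaging (default `FALSE`: flagged units are integrated as-is).
#' @return The aggregate scalar.
#' @export
aggregate_indices <- function(indices, unit_ids = indices$unit_id,
                              value = c("compliance", "amplitude_pct"),
                              exclude_flagged = FALSE) {
  value <- match.arg(value)
  sel <- indices[indices$unit_id %in% unit_ids, , drop = FALSE]
  if (exclude_flagged) sel <- sel[sel$qc_flags == "", , drop = FALSE]
  sel <- sel[is.finite(sel[[value]]), , drop = FALSE]
  if (nrow(sel) == 0) stop("empty ROI: no usable unit after QC")
  mean(sel[[value]])
}
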