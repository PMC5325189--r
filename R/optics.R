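# Optical-channel processing: normalization to percent change, 0.5-5 Hz
# band-pass, artifact masking, R-wave-locked epoch extraction and
# averaging, and baselining of the averaged pulse waveform.

#' Construct a multichannel optical recording
#'
#' @param ac Channels x samples matrix of AC light-intensity values.
#' @param fs_hz Sampling rate in Hz (default 39.0625, i.e. 25.6 ms per
#'   sample).
#' @param channel_ids Character vector of channel labels (default row
#'   names or `ch01`, `ch02`, ...).
#' @param subject_id,montage_id Optional labels.
#' @param blocks Optional data.frame with `block_id`, `start_s`, `end_s`
#'   describing recording blocks (used for split-half reliability).
#' @param geometry Optional [channel_geometry()] table covering all
#'   channels.
#' @param units `"au"` for raw intensity or `"pct"` for percent change.
#' @return An object of class `optical_recording`.
#' @export
optical_recording <- function(ac, fs_hz = 39.0625, channel_ids = NULL,
                              subject_id = NA_character_,
                              montage_id = NA_character_,
                              blocks = NULL, geometry = NULL,
                              units = c("au", "pct")) {
  units <- match.arg(units)
  ac <- as.matrix(ac)
  if (nrow(ac) < 1) stop("recording needs at least one channel")
  if (fs_hz <= 0) stop("fs_hz must be positive")
  if (is.null(channel_ids)) {
    channel_ids <- rownames(ac) %||% sprintf("ch%02d", seq_len(nrow(ac)))
  }
  if (length(channel_ids) != nrow(ac)) {
    stop("channel_ids must match the number of rows of ac")
  }
  if (!is.null(geometry) && !all(channel_ids %in% geometry$channel_id)) {
    stop("every channel_id must be present in the geometry table")
  }
  rownames(ac) <- channel_ids
  structure(list(ac = ac, fs_hz = fs_hz, channel_ids = channel_ids,
                 subject_id = subject_id, montage_id = montage_id,
                 blocks = blocks, geometry = geometry, units = units,
                 dropped_channels = character(0)),
            class = "optical_recording")
}

#' @export
print.optical_recording <- function(x, ...) {
  cat(sprintf("<optical_recording> %s: %d channels x %d samples @ %g Hz (%s)\n",
              x$subject_id, nrow(x$ac), ncol(x$ac), x$fs_hz, x$units))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `optical_recording`.
#' @export
recording_duration <- function(rec) ncol(rec$ac) / rec$fs_hz

#' Normalize channels to percent change about their own mean
#'
#' Each channel is re-expressed as `100 * (x / mean(x) - 1)`, so that a
#' cardiac fluctuation is measured in percent of the channel's mean light
#' intensity and differences in source power or detector gain cancel.
#' Channels with non-positive mean intensity cannot be normalized; they
#' are dropped and recorded in `dropped_channels`.
#'
#' @param rec An `optical_recording` in `"au"` units.
#' @return The recording in `"pct"` units.
#' @export
normalize_channels <- function(rec) {
  stopifnot(inherits(rec, "optical_recording"))
  if (rec$units == "pct") stop("recording is already normalized")
  m <- rowMeans(rec$ac)
  bad <- !is.finite(m) | m <= 0
  if (all(bad)) stop("no channel has positive mean intensity")
  if (any(bad)) {
    rec$dropped_channels <- c(rec$dropped_channels, rec$channel_ids[bad])
    warning("dropping ", sum(bad),
            " channel(s) with non-positive mean intensity: ",
            paste(rec$channel_ids[bad], collapse = ", "))
    rec$ac <- rec$ac[!bad, , drop = FALSE]
    rec$channel_ids <- rec$channel_ids[!bad]
    m <- m[!bad]
  }
  rec$ac <- 100 * sweep(rec$ac, 1, m, "/") - 100
  rec$units <- "pct"
  rec
}

#' Band-pass optical channels
#'
#' Zero-phase Butterworth band-pass (default 0.5--5 Hz) applied per
#' channel, isolating the cardiac band: slow drifts and respiratory
#' components below 0.5 Hz are removed, as is instrument noise above
#' 5 Hz.
#'
#' @param rec An `optical_recording`.
#' @param low_hz,high_hz Band edges in Hz; must lie below Nyquist
#'   (19.53 Hz at the default sampling rate).
#' @param order Butterworth order of each cascade stage.
#' @return The filtered recording.
#' @export
bandpass_optical <- function(rec, low_hz = 0.5, high_hz = 5, order = 4) {
  stopifnot(inherits(rec, "optical_recording"))
  rec$ac <- t(apply(rec$ac, 1, zero_phase_bandpass, fs_hz = rec$fs_hz,
                    low_hz = low_hz, high_hz = high_hz, order = order))
  rownames(rec$ac) <- rec$channel_ids
  rec
}

# Candidate epochs shared by reject_artifacts() and epoch_and_average():
# every beat whose full epoch fits inside the recording.  `truncated`
# marks epochs into which the next R wave intrudes.
candidate_epochs <- function(beats, rec, epoch_span_ms) {
  r <- if (inherits(beats, "beat_set")) beats$r_times_s else as.numeric(beats)
  span_s <- epoch_span_ms / 1000
  dur <- recording_duration(rec)
  inside <- r >= 0 & (r + span_s) <= dur
  # next-beat interval computed on the full beat train, not just kept beats
  nxt_all <- c(diff(r), Inf)[which(inside)]
  data.frame(time_s = r[inside], truncated = nxt_all < span_s)
}

#' Mask motion-contaminated epochs and channels
#'
#' Two robust detectors run per channel: (1) a spike/step detector on
#' sample-to-sample differences, whose scale is the MAD of the
#' differences with a floor proportional to the channel's trimmed range
#' (so a noiseless pulse train does not trigger it); (2) a baseline-shift
#' detector on the per-epoch mean over the baseline window.  Epochs
#' overlapping a flagged sample, or whose baseline is displaced by more
#' than `step_z` robust SDs, are masked.
#'
#' @param rec A normalized `optical_recording`.
#' @param beats A `beat_set` (defines the epoch grid; one column of the
#'   mask per candidate epoch).
#' @param spike_z Threshold (robust z of the differenced signal) for the
#'   spike/step detector (default 8).
#' @param step_z Threshold (robust z of per-epoch baselines) for the
#'   baseline-shift detector (default 6).
#' @param epoch_span_ms Epoch length in ms (default 1000).
#' @param baseline_window_ms Baseline window in ms (default 128--256).
#' @return A channels x epochs logical matrix (`TRUE` = keep) with
#'   attributes `log` (data.frame channel/epoch/reason) and
#'   `unusable_channels`.  A channel losing every epoch triggers a
#'   warning.
#' @export
reject_artifacts <- function(rec, beats, spike_z = 8, step_z = 6,
                             epoch_span_ms = 1000,
                             baseline_window_ms = c(128, 256)) {
  stopifnot(inherits(rec, "optical_recording"))
  if (spike_z <= 0 || step_z <= 0) stop("thresholds must be positive")
  ep <- candidate_epochs(beats, rec, epoch_span_ms)
  ne <- nrow(ep)
  nc <- nrow(rec$ac)
  keep <- matrix(TRUE, nc, ne, dimnames = list(rec$channel_ids, NULL))
  log <- list()
  t_samp <- (seq_len(ncol(rec$ac)) - 1) / rec$fs_hz
  span_s <- epoch_span_ms / 1000
  bw_s <- baseline_window_ms / 1000
  for (c_i in seq_len(nc)) {
    x <- rec$ac[c_i, ]
    d <- diff(x)
    rng <- diff(quantile(x, c(0.005, 0.995), names = FALSE))
    scale_d <- max(mad(d), 0.05 * rng, .Machine$double.eps)
    bad_samp <- which(abs(d) > spike_z * scale_d)
    bad_t <- unique(c(t_samp[bad_samp], t_samp[bad_samp + 1]))
    if (length(bad_t) && ne) {
      for (e_i in seq_len(ne)) {
        if (any(bad_t >= ep$time_s[e_i] & bad_t <= ep$time_s[e_i] + span_s)) {
          keep[c_i, e_i] <- FALSE
          log[[length(log) + 1]] <- data.frame(
            channel = rec$channel_ids[c_i], epoch = e_i, reason = "spike",
            stringsAsFactors = FALSE)
        }
      }
    }
    if (ne) {
      b <- vapply(seq_len(ne), function(e_i) {
        i <- which(t_samp >= ep$time_s[e_i] + bw_s[1] &
                     t_samp <= ep$time_s[e_i] + bw_s[2])
        mean(x[i])
      }, numeric(1))
      scale_b <- max(mad(b), 0.02 * rng, .Machine$double.eps)
      shifted <- which(abs(b - median(b)) > step_z * scale_b)
      for (e_i in shifted) {
        if (keep[c_i, e_i]) {
          keep[c_i, e_i] <- FALSE
          log[[length(log) + 1]] <- data.frame(
            channel = rec$channel_ids[c_i], epoch = e_i,
            reason = "baseline_shift", stringsAsFactors = FALSE)
        }
      }
    }
  }
  unusable <- rec$channel_ids[rowSums(keep) == 0]
  if (length(unusable)) {
    warning("unusable channel(s): every epoch masked for ",
            paste(unusable, collapse = ", "))
  }
  attr(keep, "log") <- if (length(log)) do.call(rbind, log) else
    data.frame(channel = character(0), epoch = integer(0),
               reason = character(0), stringsAsFactors = FALSE)
  attr(keep, "unusable_channels") <- unusable
  attr(keep, "epochs") <- ep
  keep
}

#' Construct an averaged pulse waveform
#'
#' @param y Averaged epoch values on the post-R time grid.
#' @param time_ms Post-R time grid in ms.
#' @param n_epochs Number of epochs averaged.
#' @param unit_id Channel or voxel label.
#' @param baseline_window_ms Window used (or to be used) for baselining.
#' @param flags Character vector of QC flags.
#' @return An object of class `pulse_waveform`.
#' @export
pulse_waveform <- function(y, time_ms, n_epochs = NA_integer_,
                           unit_id = NA_character_,
                           baseline_window_ms = c(128, 256),
                           flags = character(0)) {
  if (length(y) != length(time_ms)) stop("y and time_ms lengths differ")
  structure(list(y = as.numeric(y), time_ms = as.numeric(time_ms),
                 n_epochs = n_epochs, unit_id = unit_id,
                 baseline_window_ms = baseline_window_ms,
                 baselined = FALSE, flags = flags, annotations = list()),
            class = "pulse_waveform")
}

#' @export
print.pulse_waveform <- function(x, ...) {
  cat(sprintf(
    "<pulse_waveform> %s: %d points, %g-%g ms post-R, n_epochs=%s%s%s\n",
    x$unit_id, length(x$y), min(x$time_ms), max(x$time_ms), x$n_epochs,
    if (isTRUE(x$baselined)) ", baselined" else "",
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
    else ""))
  invisible(x)
}

#' Plot an averaged pulse waveform
#'
#' @param x A `pulse_waveform`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pulse_waveform <- function(x, ...) {
  graphics::plot(x$time_ms, x$y, type = "l", xlab = "time post-R (ms)",
                 ylab = "intensity change (%)", main = x$unit_id, ...)
  graphics::abline(v = c(384, 538), lty = 3, col = "grey50")
  invisible(x)
}

#' Extract R-wave-locked epochs and average them per channel
#'
#' For every candidate beat, channel samples are resampled (cubic spline
#' through the channel's time series) onto a common post-R grid at the
#' native sample spacing and averaged.  Epochs truncated by the next R
#' wave, or masked by [reject_artifacts()], are excluded; the count of
#' epochs actually averaged is recorded on each waveform.
#'
#' @param rec A normalized (and typically band-passed)
#'   `optical_recording`.
#' @param beats A `beat_set`.
#' @param epoch_span_ms Epoch length in ms (default 1000); must cover at
#'   least 0--600 ms post-R.
#' @param keep Optional channels x epochs mask from [reject_artifacts()].
#' @param min_epochs Minimum epochs for a trustworthy average (default
#'   100); waveforms averaging fewer are flagged `"low_epochs"`.
#' @return Named list of `pulse_waveform` objects, one per channel.
#' @export
epoch_and_average <- function(rec, beats, epoch_span_ms = 1000, keep = NULL,
                              min_epochs = 100) {
  stopifnot(inherits(rec, "optical_recording"))
  if (epoch_span_ms < 600) stop("epoch span must cover at least 0-600 ms")
  ep <- candidate_epochs(beats, rec, epoch_span_ms)
  if (nrow(ep) == 0) stop("no beat has a full epoch inside the recording")
  grid_ms <- seq(0, epoch_span_ms, by = 1000 / rec$fs_hz)
  use <- !ep$truncated
  waves <- vector("list", nrow(rec$ac))
  names(waves) <- rec$channel_ids
  n_samp <- ncol(rec$ac)
  for (c_i in seq_len(nrow(rec$ac))) {
    use_c <- use
    if (!is.null(keep)) {
      if (ncol(keep) != nrow(ep)) stop("keep mask does not match epoch count")
      use_c <- use_c & keep[c_i, ]
    }
    n_kept <- sum(use_c)
    if (n_kept == 0) {
      waves[[c_i]] <- pulse_waveform(rep(NA_real_, length(grid_ms)), grid_ms,
                                     n_epochs = 0L,
                                     unit_id = rec$channel_ids[c_i],
                                     flags = c("no_epochs", "low_epochs"))
      next
    }
    # resample every epoch onto the common post-R grid in one shot; a
    # cubic spline through the channel samples keeps the resampling
    # error far below the waveform's curvature scale
    tt <- outer(ep$time_s[use_c], grid_ms / 1000, "+")
    fch <- stats::splinefun((seq_len(n_samp) - 1) / rec$fs_hz,
                            rec$ac[c_i, ], method = "fmm")
    ymat <- fch(tt)
    dim(ymat) <- dim(tt)
    flags <- character(0)
    if (n_kept < min_epochs) flags <- "low_epochs"
    waves[[c_i]] <- pulse_waveform(colMeans(ymat), grid_ms,
                                   n_epochs = as.integer(n_kept),
                                   unit_id = rec$channel_ids[c_i],
                                   flags = flags)
  }
  if (length(waves) && any(vapply(waves, function(w)
    "low_epochs" %in% w$flags, logical(1)))) {
    warning("some channels averaged fewer than ", min_epochs, " epochs")
  }
  waves
}

#' Baseline a pulse waveform to its early-diastole window
#'
#' Subtracts the mean over the baseline window (default 128--256 ms
#' post-R, the early-diastole trough preceding the systolic upstroke of
#' the locked beat), so that waveform values are percent change relative
#' to that reference.  Idempotent.
#'
#' @param w A `pulse_waveform` whose grid covers the window.
#' @return The baselined waveform (`baselined = TRUE`).
#' @export
baseline_waveform <- function(w) {
  stopifnot(inherits(w, "pulse_waveform"))
  bw <- w$baseline_window_ms
  i <- which(w$time_ms >= bw[1] & w$time_ms <= bw[2])
  if (length(i) < 1) {
    stop("waveform grid does not cover the baseline window ",
         bw[1], "-", bw[2], " ms")
  }
  w$y <- w$y - mean(w$y[i])
  w$baselined <- TRUE
  w
}
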