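# EKG handling: container, band-pass, R-wave detection with
# interbeat-interval vetting, manual overrides, and scoring against a
# known beat train.

#' Construct an EKG trace
#'
#' A one-lead voltage series with its sampling rate.  Sample `i` is taken
#' at time `(i - 1) / fs_hz` seconds.
#'
#' @param v Numeric vector of voltages (arbitrary units).
#' @param fs_hz Sampling rate in Hz (default 1000).
#' @param subject_id Optional subject label.
#' @return An object of class `ekg_trace`.
#' @export
ekg_trace <- function(v, fs_hz = 1000, subject_id = NA_character_) {
  if (!is.numeric(v) || length(v) < 2) stop("v must be a numeric vector")
  if (!is.numeric(fs_hz) || fs_hz <= 0) stop("fs_hz must be positive")
  if (!all(is.finite(v))) stop("EKG trace contains non-finite values")
  structure(list(v = as.numeric(v), fs_hz = fs_hz,
                 subject_id = subject_id, filtered = FALSE),
            class = "ekg_trace")
}

#' @export
print.ekg_trace <- function(x, ...) {
  cat(sprintf("<ekg_trace> %s: %d samples @ %g Hz (%.1f s)%s\n",
              x$subject_id, length(x$v), x$fs_hz, length(x$v) / x$fs_hz,
              if (isTRUE(x$filtered)) ", band-passed" else ""))
  invisible(x)
}

#' Band-pass an EKG trace
#'
#' Zero-phase Butterworth band-pass (default 0.5--40 Hz), removing
#' baseline wander and high-frequency noise while leaving R-peak latency
#' unshifted.
#'
#' @param trace An [ekg_trace()].
#' @param low_hz,high_hz Band edges in Hz.
#' @param order Butterworth order of each cascade stage.
#' @return A filtered `ekg_trace` with `filtered = TRUE`.
#' @export
bandpass_ekg <- function(trace, low_hz = 0.5, high_hz = 40, order = 4) {
  stopifnot(inherits(trace, "ekg_trace"))
  trace$v <- zero_phase_bandpass(trace$v, trace$fs_hz, low_hz, high_hz, order)
  trace$filtered <- TRUE
  trace
}

#' Construct a beat set
#'
#' @param r_times_s Strictly increasing accepted R-wave times (s).
#' @param rejected data.frame with columns `time_s` and `reason`.
#' @param n_candidates Total number of candidate peaks considered.
#' @param params List of detection parameters used.
#' @return An object of class `beat_set`.
#' @export
beat_set <- function(r_times_s, rejected = empty_rejects(),
                     n_candidates = length(r_times_s), params = list()) {
  r_times_s <- as.numeric(r_times_s)
  if (is.unsorted(r_times_s, strictly = TRUE)) {
    stop("r_times_s must be strictly increasing")
  }
  structure(list(r_times_s = r_times_s, rejected = rejected,
                 n_candidates = n_candidates, params = params),
            class = "beat_set")
}

empty_rejects <- function() {
  data.frame(time_s = numeric(0), reason = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.beat_set <- function(x, ...) {
  cat(sprintf("<beat_set> %d beats accepted, %d rejected (%s)\n",
              length(x$r_times_s), nrow(x$rejected),
              if (nrow(x$rejected)) paste(names(table(x$rejected$reason)),
                                          table(x$rejected$reason),
                                          sep = ":", collapse = ", ")
              else "none"))
  if (length(x$r_times_s) > 1) {
    ibi <- diff(x$r_times_s)
    cat(sprintf("  mean HR %.1f bpm, IBI %.3f-%.3f s\n",
                60 / mean(ibi), min(ibi), max(ibi)))
  }
  invisible(x)
}

#' Detect R-wave peaks in a band-passed EKG trace
#'
#' Candidate peaks are local maxima of the standardized trace exceeding
#' `z_threshold`.  Candidates are de-duplicated within a refractory
#' window (the taller peak wins), and surviving peaks that would create
#' an interbeat interval below the plausibility band are discarded, again
#' keeping the taller of the conflicting pair.  Every discarded candidate
#' is logged with exactly one reason code ("refractory",
#' "interbeat_interval", or "manual" for later overrides), so
#' `candidates = accepted + rejected` always reconciles.
#'
#' Because the threshold applies to the standardized trace, detection is
#' invariant to multiplying the voltage by any positive constant.
#'
#' @param trace A band-passed [ekg_trace()].
#' @param z_threshold Peak threshold in standard deviations of the trace
#'   (default 3); occasionally needs per-subject adjustment.
#' @param ibi_band_s Plausible interbeat-interval range in seconds
#'   (default `c(0.4, 2)`, i.e. 30--150 bpm).
#' @param refractory_s De-duplication window in seconds (default 0.2,
#'   below the physiological minimum interbeat interval).
#' @return A `beat_set`.  Intervals longer than `ibi_band_s[2]` cannot be
#'   repaired by discarding a peak; they are reported in the `gaps`
#'   element of `params`.
#' @export
detect_rwaves <- function(trace, z_threshold = 3, ibi_band_s = c(0.4, 2),
                          refractory_s = 0.2) {
  stopifnot(inherits(trace, "ekg_trace"))
  if (!isTRUE(trace$filtered)) {
    warning("trace does not appear to be band-passed; detecting anyway")
  }
  if (z_threshold <= 0) stop("z_threshold must be positive")
  v <- trace$v
  s <- sd(v)
  if (s == 0) stop_no_beats()
  z <- (v - mean(v)) / s
  n <- length(z)
  # local maxima above threshold (plateau-tolerant on the right edge)
  is_peak <- c(FALSE, z[2:(n - 1)] > z[1:(n - 2)] &
                 z[2:(n - 1)] >= z[3:n], FALSE) & z > z_threshold
  cand <- which(is_peak)
  if (length(cand) == 0) stop_no_beats()
  t_cand <- (cand - 1) / trace$fs_hz
  a_cand <- z[cand]

  # refractory de-duplication: greedily accept peaks in decreasing height
  ord <- order(-a_cand, t_cand)
  keep <- logical(length(cand))
  acc_times <- numeric(0)
  for (i in ord) {
    if (!length(acc_times) || all(abs(acc_times - t_cand[i]) > refractory_s)) {
      keep[i] <- TRUE
      acc_times <- c(acc_times, t_cand[i])
    }
  }
  rej <- data.frame(time_s = t_cand[!keep],
                    reason = rep("refractory", sum(!keep)),
                    stringsAsFactors = FALSE)

  # interbeat-interval vetting: drop the smaller of any pair closer than
  # the lower band edge
  ti <- t_cand[keep]; ai <- a_cand[keep]
  o <- order(ti); ti <- ti[o]; ai <- ai[o]
  accepted_t <- numeric(0); accepted_a <- numeric(0)
  for (i in seq_along(ti)) {
    if (length(accepted_t) &&
        (ti[i] - accepted_t[length(accepted_t)]) < ibi_band_s[1]) {
      if (ai[i] > accepted_a[length(accepted_a)]) {
        rej <- rbind(rej, data.frame(
          time_s = accepted_t[length(accepted_t)],
          reason = "interbeat_interval", stringsAsFactors = FALSE))
        accepted_t[length(accepted_t)] <- ti[i]
        accepted_a[length(accepted_a)] <- ai[i]
      } else {
        rej <- rbind(rej, data.frame(time_s = ti[i],
                                     reason = "interbeat_interval",
                                     stringsAsFactors = FALSE))
      }
    } else {
      accepted_t <- c(accepted_t, ti[i])
      accepted_a <- c(accepted_a, ai[i])
    }
  }
  if (!length(accepted_t)) stop_no_beats()
  gaps <- which(diff(accepted_t) > ibi_band_s[2])
  beat_set(accepted_t,
           rejected = rej[order(rej$time_s), , drop = FALSE],
           n_candidates = length(cand),
           params = list(z_threshold = z_threshold, ibi_band_s = ibi_band_s,
                         refractory_s = refractory_s,
                         gaps_after_beat = gaps,
                         span_s = n / trace$fs_hz))
}

stop_no_beats <- function() {
  stop(structure(class = c("cerepulse_no_beats", "error", "condition"),
                 list(message = "no beats detected above threshold",
                      call = NULL)))
}

#' Apply manual beat edits
#'
#' Deterministically removes and/or adds R-wave times (mirroring visual
#' inspection of the detection output) and re-validates the beat-set
#' invariants: strict ordering and interbeat intervals inside the band.
#'
#' @param beats A `beat_set`.
#' @param add_times_s Times (s) to add; adding an already-present time is
#'   idempotent.
#' @param drop_times_s Times (s) to drop (matched within `tol_s`); logged
#'   under reason code "manual".
#' @param tol_s Matching tolerance for drops (default 1 ms).
#' @param ibi_band_s Interbeat-interval band re-validated after edits.
#' @return The edited `beat_set`.
#' @export
override_beats <- function(beats, add_times_s = numeric(0),
                           drop_times_s = numeric(0), tol_s = 1e-3,
                           ibi_band_s = beats$params$ibi_band_s %||% c(0.4, 2)) {
  stopifnot(inherits(beats, "beat_set"))
  span <- beats$params$span_s %||% Inf
  if (any(add_times_s < 0 | add_times_s > span)) {
    stop("added beat times fall outside the recording span")
  }
  r <- beats$r_times_s
  for (d in drop_times_s) {
    i <- which(abs(r - d) <= tol_s)
    if (!length(i)) stop("no detected beat within tol_s of ", d, " s")
    beats$rejected <- rbind(beats$rejected,
                            data.frame(time_s = r[i[1]], reason = "manual",
                                       stringsAsFactors = FALSE))
    r <- r[-i[1]]
  }
  for (a in add_times_s) {
    if (!any(abs(r - a) <= tol_s)) r <- sort(c(r, a))
  }
  if (is.unsorted(r, strictly = TRUE)) {
    stop("manual edits violate strict beat ordering")
  }
  if (length(r) > 1 && any(diff(r) < ibi_band_s[1])) {
    stop("manual edits create an interbeat interval below ",
         ibi_band_s[1], " s")
  }
  beats$r_times_s <- r
  beats$rejected <- beats$rejected[order(beats$rejected$time_s), , drop = FALSE]
  beats
}

#' Score detected beats against a known beat train
#'
#' Greedy one-to-one matching of detected to true beat times within a
#' tolerance; used to compute sensitivity, positive predictive value and
#' F1 when ground truth is available (synthetic data).
#'
#' @param beats A `beat_set` (or numeric vector of detected times).
#' @param truth_times_s True beat times in seconds.
#' @param tol_s Matching tolerance in seconds (default 0.01).
#' @return A list with `tp`, `fp`, `fn`, `sensitivity`, `ppv`, `f1`, and
#'   `match_error_s` (signed detection minus truth for matched beats).
#' @export
score_detection <- function(beats, truth_times_s, tol_s = 0.01) {
  det <- if (inherits(beats, "beat_set")) beats$r_times_s else as.numeric(beats)
  used <- logical(length(truth_times_s))
  err <- rep(NA_real_, length(det))
  for (i in seq_along(det)) {
    d <- abs(truth_times_s - det[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol_s) {
      used[j] <- TRUE
      err[i] <- det[i] - truth_times_s[j]
    }
  }
  tp <- sum(used); fp <- length(det) - tp; fn <- length(truth_times_s) - tp
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (is.na(sens) || is.na(ppv) || sens + ppv == 0) NA_real_ else
    2 * sens * ppv / (sens + ppv)
  list(tp = tp, fp = fp, fn = fn, sensitivity = sens, ppv = ppv, f1 = f1,
       match_error_s = err[!is.na(err)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
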