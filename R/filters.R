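# Zero-phase band-pass filtering shared by the EKG and optical stages.
#
# A single Butterworth band-pass whose lower edge sits at ~1e-3 of Nyquist
# (0.5 Hz on a 1000 Hz EKG) is numerically fragile in transfer-function
# form, so the band is realised as a low-pass/high-pass cascade, each run
# forward-backward (filtfilt) so that peak latencies are not shifted.

#' Zero-phase Butterworth band-pass
#'
#' Applies a low-pass at `high_hz` followed by a high-pass at `low_hz`,
#' each as a forward-backward (zero-phase) Butterworth pass, so the
#' effective roll-off is twice the nominal `order` and no group delay is
#' introduced.
#'
#' @param x Numeric vector, the signal to filter.
#' @param fs_hz Sampling rate in Hz.
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < fs_hz / 2`.
#' @param order Butterworth order of each cascade stage (default 4).
#' @return Numeric vector of the same length as `x`.
#' @keywords internal
zero_phase_bandpass <- function(x, fs_hz, low_hz, high_hz, order = 4) {
  ny <- fs_hz / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < ny)) {
    stop("band edges must satisfy 0 < low_hz < high_hz < fs_hz/2 (Nyquist ",
         ny, " Hz)", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("signal contains non-finite values", call. = FALSE)
  lp <- signal::butter(order, high_hz / ny, type = "low")
  hp <- signal::butter(order, low_hz / ny, type = "high")
  y <- signal::filtfilt(lp, x)
  signal::filtfilt(hp, y)
}
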