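# Plain-text (CSV) interchange for every stage, used by the command-line
# driver and for archiving: EKG traces, optical recordings, geometry,
# beat sets, waveforms, indices and cohort tables.

#' Write / read an EKG trace as CSV
#'
#' Two columns: `time_s`, `v`.  The sampling rate is recovered from the
#' time column on read.
#'
#' @param trace An [ekg_trace()].
#' @param path CSV path.
#' @export
write_ekg_csv <- function(trace, path) {
  stopifnot(inherits(trace, "ekg_trace"))
  df <- data.frame(time_s = (seq_along(trace$v) - 1) / trace$fs_hz,
                   v = trace$v)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ekg_csv
#' @param subject_id Label attached on read.
#' @export
read_ekg_csv <- function(path, subject_id = NA_character_) {
  df <- read.csv(path)
  if (!all(c("time_s", "v") %in% names(df))) {
    stop("EKG CSV needs columns time_s, v")
  }
  fs <- 1 / median(diff(df$time_s))
  ekg_trace(df$v, fs_hz = fs, subject_id = subject_id)
}

#' Write / read an optical recording as CSV
#'
#' Wide format: `time_s` plus one column per channel.
#'
#' @param rec An [optical_recording()].
#' @param path CSV path.
#' @export
write_optical_csv <- function(rec, path) {
  stopifnot(inherits(rec, "optical_recording"))
  df <- data.frame(time_s = (seq_len(ncol(rec$ac)) - 1) / rec$fs_hz)
  for (i in seq_len(nrow(rec$ac))) df[[rec$channel_ids[i]]] <- rec$ac[i, ]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_optical_csv
#' @param subject_id Label attached on read.
#' @param units Units of the stored values.
#' @export
read_optical_csv <- function(path, subject_id = NA_character_,
                             units = "au") {
  df <- read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) stop("optical CSV needs a time_s column")
  fs <- 1 / median(diff(df$time_s))
  ch <- setdiff(names(df), "time_s")
  ac <- t(as.matrix(df[ch]))
  optical_recording(ac, fs_hz = fs, channel_ids = ch,
                    subject_id = subject_id, units = units)
}

#' Write / read channel geometry as CSV
#'
#' @param geom A [channel_geometry()].
#' @param path CSV path.
#' @export
write_geometry_csv <- function(geom, path) {
  stopifnot(inherits(geom, "channel_geometry"))
  write.csv(as.data.frame(geom), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_geometry_csv
#' @export
read_geometry_csv <- function(path) {
  channel_geometry(read.csv(path, stringsAsFactors = FALSE))
}

#' Write a beat set as CSV
#'
#' Long format with one row per candidate: `time_s`, `status`
#' (`accepted`/rejection reason).
#'
#' @param beats A `beat_set`.
#' @param path CSV path.
#' @export
write_beats_csv <- function(beats, path) {
  stopifnot(inherits(beats, "beat_set"))
  df <- rbind(data.frame(time_s = beats$r_times_s, status = "accepted",
                         stringsAsFactors = FALSE),
              data.frame(time_s = beats$rejected$time_s,
                         status = beats$rejected$reason,
                         stringsAsFactors = FALSE))
  df <- df[order(df$time_s), , drop = FALSE]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beats_csv
#' @export
read_beats_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  acc <- df$time_s[df$status == "accepted"]
  rej <- df[df$status != "accepted", , drop = FALSE]
  beat_set(sort(acc),
           rejected = data.frame(time_s = rej$time_s, reason = rej$status,
                                 stringsAsFactors = FALSE))
}

#' Write averaged waveforms as CSV
#'
#' Long format: `unit_id`, `time_ms`, `y`, `n_epochs`, `flags`.
#'
#' @param waveforms Named list of `pulse_waveform` objects.
#' @param path CSV path.
#' @export
write_waveforms_csv <- function(waveforms, path) {
  df <- do.call(rbind, lapply(waveforms, function(w) {
    data.frame(unit_id = w$unit_id, time_ms = w$time_ms, y = w$y,
               n_epochs = w$n_epochs,
               flags = paste(w$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveforms_csv
#' @param baselined Whether the stored waveforms were baselined.
#' @export
read_waveforms_csv <- function(path, baselined = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$unit_id), function(d) {
    d <- d[order(d$time_ms), , drop = FALSE]
    w <- pulse_waveform(d$y, d$time_ms, n_epochs = d$n_epochs[1],
                        unit_id = d$unit_id[1],
                        flags = if (nzchar(d$flags[1]))
                          strsplit(d$flags[1], ";")[[1]] else character(0))
    w$baselined <- baselined
    w
  })
  out[order(names(out))]
}
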