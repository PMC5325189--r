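# End-to-end processing of one subject and of a whole (synthetic or
# ingested) cohort: R-wave detection -> channel selection ->
# normalization -> (optional) band-pass -> artifact masking -> epoch
# averaging -> baselining -> per-channel indices -> global and regional
# aggregates.

#' Process one subject end to end
#'
#' @param optical An [optical_recording()] in `"au"` units.
#' @param ekg The subject's [ekg_trace()].
#' @param geometry A [channel_geometry()] (default the recording's own).
#' @param bandpass Apply the 0.5--5 Hz optical band-pass (default
#'   `TRUE`).
#' @param artifact_rejection Mask motion-contaminated epochs (default
#'   `TRUE`).
#' @param z_threshold R-wave detection threshold.
#' @param epoch_span_ms,min_epochs Epoching parameters.
#' @param time_range_s Optional `c(start, end)`: only beats inside this
#'   window contribute epochs (used for per-block processing).
#' @param rois Named list of [roi_spec()]s to aggregate over (default
#'   global box + frontoparietal + visual label ROIs).
#' @param exclude_flagged Drop QC-flagged channels from aggregates.
#' @return A list of class `subject_result`: `beats`, `waveforms`,
#'   `indices` (per channel), `aggregates` (data.frame roi/value per
#'   index), and `qc` (channel counts at every stage).
#' @export
process_subject <- function(optical, ekg, geometry = optical$geometry,
                            bandpass = TRUE, artifact_rejection = TRUE,
                            z_threshold = 3, epoch_span_ms = 1000,
                            min_epochs = 100, time_range_s = NULL,
                            rois = list(global = roi_global(),
                                        frontoparietal = roi_frontoparietal(),
                                        visual = roi_visual()),
                            exclude_flagged = FALSE) {
  stopifnot(inherits(optical, "optical_recording"))
  if (is.null(geometry)) stop("a channel geometry is required")
  beats <- detect_rwaves(bandpass_ekg(ekg), z_threshold = z_threshold)
  if (!is.null(time_range_s)) {
    keep_b <- beats$r_times_s >= time_range_s[1] &
      beats$r_times_s <= time_range_s[2]
    beats$r_times_s <- beats$r_times_s[keep_b]
    if (!length(beats$r_times_s)) stop("no beats inside time_range_s")
  }
  geom <- filter_channels(geometry)
  n_total <- nrow(geometry)
  rec <- optical
  sel <- rec$channel_ids %in% geom$channel_id
  rec$ac <- rec$ac[sel, , drop = FALSE]
  rec$channel_ids <- rec$channel_ids[sel]
  rec <- normalize_channels(rec)
  if (bandpass) rec <- bandpass_optical(rec)
  keep <- NULL
  if (artifact_rejection) {
    keep <- reject_artifacts(rec, beats, epoch_span_ms = epoch_span_ms)
  }
  waves <- epoch_and_average(rec, beats, epoch_span_ms = epoch_span_ms,
                             keep = keep, min_epochs = min_epochs)
  waves <- lapply(waves, baseline_waveform)
  idx <- indices_per_unit(waves)
  geom_used <- geom[match(idx$unit_id, geom$channel_id), , drop = FALSE]
  agg <- do.call(rbind, lapply(names(rois), function(nm) {
    member <- tryCatch(assign_units(geom_used, rois[[nm]]),
                       cerepulse_empty_roi = function(e) NULL)
    if (is.null(member)) {
      return(data.frame(roi = nm, n_units = 0L, compliance = NA_real_,
                        amplitude_pct = NA_real_, stringsAsFactors = FALSE))
    }
    ids <- idx$unit_id[member]
    data.frame(
      roi = nm, n_units = sum(member),
      compliance = aggregate_indices(idx, ids, "compliance",
                                     exclude_flagged = exclude_flagged),
      amplitude_pct = aggregate_indices(idx, ids, "amplitude_pct",
                                        exclude_flagged = exclude_flagged),
      stringsAsFactors = FALSE)
  }))
  qc <- list(n_channels_total = n_total,
             n_channels_distance_ok = nrow(geom),
             n_channels_normalized = length(rec$channel_ids),
             n_beats = length(beats$r_times_s),
             n_beats_rejected = nrow(beats$rejected),
             n_epochs_masked = if (is.null(keep)) 0L else sum(!keep),
             unusable_channels = if (is.null(keep)) character(0) else
               attr(keep, "unusable_channels"))
  structure(list(beats = beats, waveforms = waves, indices = idx,
                 aggregates = agg, qc = qc,
                 subject_id = optical$subject_id),
            class = "subject_result")
}

#' @export
print.subject_result <- function(x, ...) {
  cat(sprintf("<subject_result> %s: %d beats, %d channels\n",
              x$subject_id, x$qc$n_beats, nrow(x$indices)))
  print(x$aggregates, row.names = FALSE)
  invisible(x)
}

roi_value <- function(res, roi, what = "compliance") {
  v <- res$aggregates[[what]][res$aggregates$roi == roi]
  if (length(v)) v else NA_real_
}

#' Simulate and process a whole cohort
#'
#' Generates each subject's recordings from the configuration, runs
#' [process_subject()] on them, and augments the cohort table with the
#' estimated indices (`est_amplitude`, `est_compliance`,
#' `est_compliance_frontoparietal`, `est_compliance_visual`, and the
#' per-block global values `est_amplitude_b1/b2`,
#' `est_compliance_b1/b2` when `split_blocks = TRUE`) plus `ecrf_mets`.
#' Recordings are generated and discarded one subject at a time, so
#' memory stays flat in cohort size.
#'
#' @param config A [sim_config()].
#' @param split_blocks Also compute per-block global indices for
#'   split-half reliability (doubles the epoching work; default
#'   `FALSE`).
#' @param ... Passed to [process_subject()].
#' @return The cohort data.frame with estimate columns appended.
#' @export
process_cohort <- function(config = sim_config(), split_blocks = FALSE, ...) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  geometry <- make_montage(config$n_channels)
  cohort <- cohort_covariates(config)
  cohort$ecrf_mets <- compute_ecrf(cohort)
  est <- lapply(seq_len(nrow(cohort)), function(i) {
    sub <- simulate_subject(config, cohort[i, ], geometry)
    res <- process_subject(sub$optical, sub$ekg, geometry, ...)
    out <- data.frame(
      est_amplitude = roi_value(res, "global", "amplitude_pct"),
      est_compliance = roi_value(res, "global", "compliance"),
      est_compliance_frontoparietal = roi_value(res, "frontoparietal"),
      est_compliance_visual = roi_value(res, "visual"))
    if (split_blocks) {
      halves <- lapply(seq_len(2), function(b) {
        rng <- unlist(sub$optical$blocks[b, c("start_s", "end_s")])
        process_subject(sub$optical, sub$ekg, geometry,
                        time_range_s = rng, min_epochs = 50, ...)
      })
      out$est_amplitude_b1 <- roi_value(halves[[1]], "global", "amplitude_pct")
      out$est_amplitude_b2 <- roi_value(halves[[2]], "global", "amplitude_pct")
      out$est_compliance_b1 <- roi_value(halves[[1]], "global")
      out$est_compliance_b2 <- roi_value(halves[[2]], "global")
    }
    out
  })
  cbind(cohort, do.call(rbind, est))
}
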