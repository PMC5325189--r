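Package: cerepulse
Title: Cerebral Pulse Waveforms and Arterial Compliance from Diffuse
    Optical Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for extracting EKG-locked cerebral pulse waveforms from
    multichannel diffuse optical (near-infrared) intensity recordings and
    deriving two cerebrovascular indices from them: pulse amplitude (the
    mean baselined percent-change intensity in the systolic window) and
    arterial compliance (the time- and amplitude-normalized area under the
    diastolic limb of the pulse, minus 0.5).  Includes R-wave detection
    with interbeat-interval vetting, artifact rejection, channel geometry
    handling with source-detector distance filtering and region-of-interest
    aggregation, cohort-level statistics (estimated cardiorespiratory
    fitness, outlier exclusion, split-half reliability, partial
    correlation, residual-variance analysis, percentile-bootstrap
    mediation), and a seeded synthetic-cohort generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
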