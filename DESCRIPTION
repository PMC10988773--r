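Package: fpvstag
Title: Frequency-Tagged EEG Analysis for Fast Periodic Visual Stimulation Oddball Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing fast periodic
    visual stimulation (FPVS) oddball EEG experiments. Provides
    constraint-aware oddball stimulus sequence scheduling with orthogonal
    go/no-go task events, a multi-channel synthetic EEG generator with
    1/f background noise and known periodic responses, the standard
    frequency-tagging preprocessing chain (FFT band-pass, segmentation,
    resampling, bad-channel interpolation, average reference,
    cycle-aligned cropping), high-resolution amplitude spectra, and the
    neighbouring-bin noise statistics used to quantify oddball responses
    (signal-to-noise ratio, baseline-subtracted amplitude, Z-scores,
    harmonic selection and summation), together with region-of-interest
    aggregation, individual-level significance tables and behavioural
    scoring.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
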