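Package: WormSleep
Title: Sleep Bout Segmentation, ALA Calcium Dynamics and Sleep Homeostasis
    in C. elegans Lethargus
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing developmentally timed sleep (lethargus) in
    Caenorhabditis elegans from video and dual-channel fluorescence
    recordings. Scores per-frame locomotor activity by image subtraction
    with empty-chamber threshold calibration, segments recordings into
    alternating sleep and motion bouts, computes ratiometric GCaMP/RFP
    fractional-change (dR/R0) traces, performs bout-aligned and
    duration-normalized averaging, transition-triggered windows and
    peak-latency correlation analysis, quantifies sleep homeostasis
    (sleep-bout duration versus prior motion-bout duration), and analyses
    optogenetic stimulation-aligned behaviour. Includes a synthetic-data
    generator producing bout schedules, calcium traces, rendered worm
    videos and optogenetic trials with known ground truth for validation.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
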