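Package: necroquant
Title: Quantification of Calcium and Phosphatidylserine Dynamics in
    Necrotic Cell Time-Lapse Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of two-channel fluorescence
    time-lapse recordings of cells undergoing excitotoxic necrosis, as in
    C. elegans touch-neuron degeneration. Implements polygon and
    donut-annulus region measurement with background-relative intensity
    ratios for a surface phosphatidylserine (PS) reporter and a cytoplasmic
    calcium indicator, event-onset detection (calcium rise, cell swelling,
    PS appearance), trapezoidal integration of irregularly sampled
    intensity traces over named time windows, cohort statistics
    (reference-normalized intensities, grouped necrotic-cell counts,
    PS-positive fractions, dose-response tables), and log-log regression
    between integrated calcium and PS signals. A fully ground-truthed
    synthetic scene generator renders two-channel image stacks so that
    every stage of the pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    readxl,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
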