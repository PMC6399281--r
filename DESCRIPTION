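Package: difc
Title: Dual-Probe Diffuse In Vivo Flow Cytometry Signal Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for diffuse in vivo flow cytometry (DiFC)
    traces: two-channel fluorescence trace simulation with known ground
    truth, background estimation and smoothing, threshold-and-prominence
    peak-candidate detection with interpolated peak widths, arterial/venous
    coincidence matching across the two fiber probes, and downstream
    quantification (count rates, false-alarm rates, signal-to-noise ratio,
    cell speed and depth estimates, concentration conversion) together with
    reference-microsphere threshold calibration and blood-sample counting.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
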