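Package: sparsegate
Title: Calcium-Transient Detection and Population Activation Analysis for
    Dentate Granule Cell Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multicellular calcium imaging of hippocampal dentate
    granule cells: derivative-threshold detection and characterization of
    stimulus-evoked somatic calcium transients in ROI fluorescence traces,
    viability filtering and proportional-activation statistics at the slice
    and group level, granule-cell-layer position analysis, action-potential
    latency measurement from juxtacellular recordings, and the accompanying
    nonparametric statistical battery (Kruskal-Wallis with Dunn post hoc,
    Brown-Forsythe, Fisher exact, robust FDR-based outlier elimination).
    Includes a calibrated synthetic-data generator producing fluorescence
    traces, population datasets and voltage traces with ground truth, so the
    whole pipeline is testable without raw recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    tiff,
    car,
    multcomp,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
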