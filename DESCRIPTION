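Package: endocal
Title: Single-Cell Calcium Imaging Analysis for En Face Endothelium
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event analysis for single-cell Ca2+ imaging of native endothelium.
    Converts fluorescence movie stacks and cell label maps into per-cell F/F0
    traces, detects Ca2+ release events with a Savitzky-Golay smoothed
    derivative zero-crossing detector, reduces them to per-cell amplitude,
    oscillation and duration metrics, and aggregates cells over technical and
    biological replicates with log-scale paired statistics and two-way ANOVA
    with Tukey contrasts. Includes a synthetic movie generator with condition
    presets (flash-photolysis IP3 uncaging, agonist perfusion, endothelial
    patch protocols) and per-event ground truth, so every stage of the
    pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    tiff,
    jsonlite,
    yaml,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
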