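Package: clicknet
Title: Unsupervised Network-Based Classification of Delphinid Echolocation Clicks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and classifying delphinid echolocation click
    types in wideband passive acoustic recordings. Implements an energy-threshold
    click detector with spectral and envelope quality control, spectral-similarity
    networks clustered with the Chinese Whispers label-propagation algorithm
    within five-minute time bins, consensus clustering of per-bin summary nodes
    (mean spectrum and modal inter-click interval) across recording sites using
    normalized mutual information and Best-of-K selection, and template-based
    classification of novel data with certainty scoring. Includes a synthetic
    data generator that produces ground-truthed click waveforms, audio scenes and
    detection-level datasets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
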