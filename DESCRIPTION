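Package: measort
Title: Spike Detection, Sorting and Evoked-Response Identification for
    Microelectrode Array Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for extracellular recordings from
    microelectrode arrays (MEAs) under electrical stimulation: stimulus
    artifact blanking, spike detection by stationary wavelet transform and
    the Teager energy operator with data-driven threshold optimization,
    spike sorting by stationary wavelet-packet features and K-means with
    silhouette-based model selection, classification of units as
    electrically responsive from per-trial rasters, and spatial (electrode
    layer) and voltage-response characterization with Boltzmann sigmoid
    fitting. Includes a ground-truthed synthetic MEA recording generator
    so every stage can be validated without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    signal,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
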