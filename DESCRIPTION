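Package: hindscope
Title: Swim- and Stimulus-Triggered Analysis of Hindbrain Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for single-plane two-photon calcium
    imaging of the larval zebrafish hindbrain during optomotor swimming.
    Converts high-speed tail tracking into bend-angle traces and swim
    bouts, corrects red-to-green fluorophore bleed-through, computes
    ROI delta-F-over-F traces, builds swim-triggered and
    stimulus-triggered averages, classifies traces as swim-driven or
    stimulus-driven by mean event-wise correlation, clusters triggered
    averages into activity archetypes by correlation-threshold
    clustering, and maps cluster centroids back onto the movie as
    per-pixel event-averaged correlation maps. Includes a seeded
    synthetic-experiment generator with ground-truth bouts, ROI
    footprints and activity archetypes so that every stage can be
    validated against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    zoo,
    jsonlite,
    yaml,
    tiff,
    S4Vectors,
    SummarizedExperiment
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
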