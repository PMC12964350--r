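Package: arenatrack
Title: Multi-Animal Arena Tracking, Posture Classification and Trajectory
    Quality Control
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies locomotion of multiple animals (e.g. Drosophila
    larvae) filmed in a circular arena. Converts per-frame binary
    segmentation masks into calibrated shape and movement features
    (centroid, area, fitted ellipse, major/minor axis ratio), classifies
    posture into elongated and bent states from the per-track z-scored
    axis-ratio distribution, detects and excises six classes of tracking
    failure (static detachment, collision merges, gradual size drift,
    identity switches, statistical outliers and duplicate tracks), and
    aggregates per-track distance, speed, state-resolved and
    length-normalised summaries. Includes a deterministic classical
    segmentation backend behind a pluggable contract and a synthetic
    scene generator with ground-truth failure injection, so the entire
    pipeline is testable without any foundation model or video download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
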