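Package: lcrtracker
Title: Detection, Classification and Tracking of Local Calcium Releases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Automatic detection, classification and tracking of local
    calcium releases (LCRs) in time series of two-dimensional submembrane
    calcium concentration frames, such as those produced by stochastic
    sinoatrial-node cell simulations or high-speed camera recordings.
    Single-frame release footprints are segmented by adaptive intensity
    binning into nested supra-threshold clusters with per-cluster peak
    counting; footprints are linked across frames by spatial overlap into
    dynamic LCRs, including births, deaths by stochastic attrition,
    collisions resolved by signal mass, separations into multiple threads,
    and termination typing. Per-event statistics (signal mass, path area,
    maximum amplitude, duration, birth time) and ensemble summaries are
    computed over a diastolic analysis window selected from a membrane
    potential trace. A seeded synthetic frame generator renders scripted
    Gaussian release events over a decaying background with exact ground
    truth, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tiff,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'frames-io.R'
    'segmentation.R'
    'tracking.R'
    'metrics.R'
    'window.R'
    'synth.R'
    'pipeline.R'
    'lcrtracker-package.R'
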