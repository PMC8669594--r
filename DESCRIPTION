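Package: graspsource
Title: Source-Space Decoding and Network Analysis of Reach-and-Grasp EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for natural reach-and-grasp
    decoding from low-frequency EEG. Generates synthetic multichannel
    recordings carrying movement-related cortical potentials (MRCP) with
    known ground truth, detects movement onsets from button/force channels,
    applies the standard MRCP preprocessing chain (zero-phase Butterworth
    filtering, downsampling, epoching, amplitude/joint-probability/kurtosis
    trial rejection, common average reference), projects epochs onto 24
    Brodmann-area regions of interest with an sLORETA inverse operator,
    decodes six movement conditions with sliding-window shrinkage-LDA
    classifiers under repeated stratified cross-validation, and
    characterises phase-locking-value functional networks with weighted
    graph metrics (mean degree, density, modularity, clustering
    coefficient, characteristic path length).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
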