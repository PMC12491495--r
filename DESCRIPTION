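Package: paintbench
Title: Simulation and Quantitative Analysis of Multiplexed DNA-PAINT
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Synthetic-data generation and analysis for speed-optimized
    left-/right-handed DNA-PAINT multiplexing benchmarks. Generates
    ground-truth structures (DNA origami grids, Nup96 nuclear-pore
    standards, filaments) and Exchange-PAINT localization tables from
    two-state binding kinetics with drift, fiducials and crosstalk, and
    analyzes them: fiducial drift correction, cross-correlation channel
    alignment and tile stitching, fixed-radius binding-site clustering
    with temporal frame filtering, bright/dark-time kinetics with
    concentration and site-count normalization, NeNA localization
    precision, geometry metrics (site spacing, ring separation, filament
    diameter), crosstalk matrices, a throughput model for sequential
    multiplexing, and docking-strand library checks (concatemer
    construction, hairpin stems, cross-hybridization).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    mclust,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    rhdf5,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
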