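Package: eamtools
Title: Electroanatomic Mapping Data Containers and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A compact exchange container and analysis toolkit for
    electroanatomic mapping (EAM) studies: a triangulated chamber surface
    with per-vertex local activation time and bipolar voltage fields,
    per-point intracardiac electrograms with their annotations and windows
    of interest, and radiofrequency ablation (visitag) records. Provides a
    parser for a documented clinical-export-style file dialect, chamber
    geometry metrics (surface area with and without anatomical cut-outs,
    volume, free-boundary detection, point status), scattered-data
    interpolation of activation and voltage fields onto the surface,
    radial-basis-function conduction velocity mapping, total activation
    time and earliest-activation-site metrics, voltage and conduction
    velocity histogram analysis with exact sub-triangle areas, ablation
    area quantification, electrogram and map plotting, a seeded synthetic
    fixture generator with known ground truth, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    xml2,
    jsonlite,
    tibble,
    dplyr,
    generics,
    rlang,
    ggplot2,
    stats,
    utils,
    tools,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
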