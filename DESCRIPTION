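Package: reefconn
Title: Lagrangian Larval Dispersal and Reef Connectivity Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Biophysical simulation of larval dispersal over gridded or
    analytic ocean current fields, and the connectivity statistics built on
    it. Provides a two-dimensional Lagrangian advection-diffusion particle
    tracker with a habitat-settlement rule (fixed pelagic larval duration,
    settlement within a radius of a habitat pixel center), habitat grids
    with island grouping and great-circle distance matrices, settlement and
    probability (rearward/forward) connectivity matrices, self-recruitment,
    source-sink indices, dispersal-distance kernels, settlement time series,
    seasonal subsets, permutation Mantel matrix comparisons, and a family of
    synthetic flow/habitat scenarios with analytic expectations for
    validating the whole pipeline without external ocean-model output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    geosphere,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
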