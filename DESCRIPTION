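Package: zincagg
Title: Zinc-Induced Peptide Aggregation Analysis for Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for zinc-induced self-assembly of short amyloid
    peptides in periodic simulation boxes. Detects molecular complexes as
    connected components of a minimum-image contact graph, scores aggregation
    with the connectivity-length statistic (the sum of square roots of complex
    sizes), classifies zinc coordination-shell motifs (zinc-bridged dimers
    versus closed monomeric sites), detects zinc recapture events, and builds
    free-energy landscapes over reaction-coordinate pairs such as RMSD and
    radius of gyration. Includes readers and writers for PDB, multi-frame GRO
    and a box-aware XYZ dialect, and a coarse-grained Brownian sticky-sphere
    simulator that generates aggregation trajectories with the statistical
    structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    bio3d,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
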