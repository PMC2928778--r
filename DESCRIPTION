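Package: ibcell
Title: Immersed-Boundary Simulation of Epithelial Acinar Morphogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Deterministic agent-based simulation of epithelial acinus
    formation in which fully deformable cells, represented as elastic
    spring polygons immersed in a viscous incompressible fluid, grow,
    divide, polarize and die according to the configuration of labelled
    membrane receptors (growth sensors, cell-cell adhesion receptors,
    ECM receptors, apical markers and death receptors). Includes a
    spectral Stokes solver on a periodic grid coupled to Lagrangian
    boundaries through a regularized delta function, receptor-threshold
    phenotype rules with ECM secretion/decay kinetics, morphology
    quantification and four-class classification, threshold-space
    morphochart sweeps, and a stagewise search-tree tuner that fits
    simulated cell-count timelines to experimental tables from 3D
    MCF10A and HER2-mutant cultures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
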