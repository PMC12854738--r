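Package: ktnr
Title: Kinetic Transition Network Analysis for RNA Energy Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing potential energy landscapes represented as
    kinetic transition networks (KTNs): reading and writing stationary-point
    databases, harmonic-superposition thermodynamics (occupation
    probabilities, free energies, heat-capacity curves), harmonic
    transition-state-theory kinetics with Eyring barrier conversions and
    mean-first-passage-time effective rates, free-energy regrouping of minima
    into kinetic groups, disconnectivity-graph construction with funnel
    selection and order-parameter colouring, and structural descriptors for
    RNA ensembles (Leontis-Westhoff base-pair annotation, sugar pucker
    pseudorotation, inter-helical angles, solvent-accessible surface area,
    PCA). A desk-scale stationary-point search (doubly nudged elastic band,
    hybrid eigenvector-following, steepest-descent connection) on pluggable
    analytic potentials builds KTNs end to end, and seeded generators provide
    synthetic landscapes and RNA fixtures with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite,
    withr
Config/testthat/edition: 3
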