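Package: pentadyn
Title: Coarse-Grained Conformational Analysis of Pentameric Ligand-Gated Ion Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for coarse-grained structural analysis of pentameric
    ligand-gated ion channels (pLGICs): principal component analysis of
    superposed structural ensembles with trajectory projection and relative
    free-energy landscapes, elastic-network normal modes (cutoff ANM and a
    sequence-distance calibrated variant) with residue fluctuations, overlap
    metrics between mode spaces and experimental transition vectors,
    heuristic channel descriptors (quaternary twist, ECD blooming, TM2
    tilt/twist, pore-radius profiles, hydration and ion permeation),
    conservation-weighted 3D mutation clustering, and GROMOS-style RMSD
    conformational clustering. Includes a synthetic-data generator that
    builds C5-symmetric toy pentamers with known ground truth so every
    stage of the pipeline can be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    igraph,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
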