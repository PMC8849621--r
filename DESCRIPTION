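Package: cladomorph
Title: Maximum-Parsimony Phylogenetics and Skeletal Morphometrics for
    Fragmentary Theropod Material
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative workflow used in descriptive work on
    fragmentary theropod (especially spinosaurid) skeletons: parsing, merging
    and editing discrete morphological character matrices (TNT and NEXUS
    dialects); maximum-parsimony tree search with Fitch/Hartigan optimization,
    strict consensus, maximum agreement subtrees, bootstrap and Bremer decay
    supports, ensemble consistency and retention indices, and synapomorphy
    mapping; principal component analysis of tooth and pedal-ungual
    measurement tables with convex-hull morphospace membership and dentary
    alveolus profiling; and seriation of associated caudal vertebrae via the
    Anterior Surface Index (ASI) with template-based position assignment under
    diapophysis constraints. Ships deterministic synthetic-data generators so
    every analysis stage is testable without external files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
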