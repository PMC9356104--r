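Package: enscape
Title: Energy Landscapes of Logical Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Maps a signed gene regulatory network together with a
    configuration of three-valued logical operators onto a discrete energy
    landscape over all 2^N binary cell states, and analyzes that landscape.
    Provides the three-valued operator algebra (effect space {-1,0,+1},
    brute-force operator enumeration under idempotence, commutativity and
    associativity), redundancy-free enumeration and stochastic sampling of
    operator expression trees, attractor and basin-of-attraction detection
    with degenerate-plateau semantics, exact multilinear (pseudo-Boolean)
    interpolation of the landscape with entropy and free energy,
    Boltzmann-weighted random-walk ("marble") simulations of cell-state
    transitions and reprogramming, flattened-hypercube landscape
    visualization, and a command-line workflow for searching operator
    configurations against binarized expression constraints.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
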