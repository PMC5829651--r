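Package: supercoilex
Title: Supercoiling-Driven Chromatin Loop Extrusion Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Coarse-grained Brownian dynamics of a twistable worm-like-chain
    chromatin fibre in which transcription-induced negative supercoiling,
    injected by active swivels and dissipated by passive swivels and phantom
    (strand-passage) regions at domain borders, drives cohesin-handcuff
    chromatin loop extrusion across a TAD-sized fibre. Includes topological
    observables (twist, Gauss-integral writhe, linking-number bookkeeping,
    plectoneme detection, loop extent, contact maps, persistence-length
    recovery), programmatic scenario builders, trajectory and configuration
    input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
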