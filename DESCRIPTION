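Package: chromatx
Title: Polymer Simulation of Transcription and Emergent Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fitting-free 3D polymer model of transcription. A chromatin
    fibre is represented as a bead-and-spring chain in which some beads are
    transcription units (TUs); spheres representing complexes of transcription
    factors and polymerases (TFs) bind multivalently to the chain and switch
    stochastically between an active (binding) and inactive (non-binding)
    state. The system is evolved by underdamped Langevin dynamics with a
    compiled velocity-Verlet engine. A TU is scored as transcribed whenever an
    active TF lies close to it, which yields per-TU activity profiles,
    transcriptional bursting statistics, and emergent regulatory networks
    obtained by correlating activities across replicate simulations. The
    package also supports in-silico perturbations (TU knockouts, permanent
    loops, heterochromatin islands, region deletions), genome-annotation
    driven whole-chromosome simulations (DNase-hypersensitive-site and
    chromatin-state bead classification, ellipsoidal chromosome territories),
    and utilities to compare simulated activity with experimental signal
    tracks and Hi-C-like contact maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    withr,
    methods,
    BiocGenerics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
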