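Package: biomevol
Title: Macroevolution of Microbial Biome Specialization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how microbial lineages specialize on and
    transition between biomes on a phylogeny. Implements an occupancy
    bootstrap classifier assigning taxa to biome preferences from
    presence/absence across biome-labelled samples, community clustering of
    samples into biomes (weighted UniFrac, principal coordinates restricted
    to positive eigenvalues, PERMANOVA with pairwise FDR, k-medoid
    clustering with the gap statistic), multistate Markov (Mk) models of
    biome-preference evolution with iterative model simplification and
    source-sink statistics, and multistate/hidden-state
    speciation-extinction (MuSSE, MuHiSSE, CTD) models testing whether
    diversification depends on biome preference. Forward simulators for
    birth-death trees, Mk trait histories, state-dependent diversification
    and biome-structured occupancy tables provide ground-truthed synthetic
    data for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    cluster,
    phangorn,
    phyloseq,
    Rcpp,
    stats,
    utils,
    vegan,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    Matrix,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
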