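Package: topofilter
Title: Sitewise Topology Signal and Targeted Site Filtering for
    Phylogenomic Supermatrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the phylogenetic signal of individual alignment
    sites for competing resolutions of a contested node. Computes per-site
    log-likelihoods of a protein supermatrix under fixed candidate
    topologies with the LG+F+Gamma model (Felsenstein pruning, discrete
    Gamma rate heterogeneity, per-topology branch-length and shape
    optimization), scores each site by the log-likelihood gap between the
    best and second-best topology (dlnL), classifies strong and weak
    sites, removes strong sites favoring chosen topologies, and
    re-evaluates the candidate topologies on the filtered matrix.
    Includes Robinson-Foulds distances, supermatrix occupancy and
    trimming diagnostics, a parser for externally computed per-site
    likelihood files, and a simulator of supermatrices with planted
    topology signal for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
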