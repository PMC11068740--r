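Package: minicom
Title: Function-Specific Minimal Microbial Communities from Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Identifies minimal sub-communities of a microbial community that
    retain a user-defined fraction of the full community's growth rate and
    short-chain-fatty-acid (SCFA) production.  Per-species genome-scale
    metabolic models are merged into a compartmentalised community model with
    a shared metabolite pool, community growth is computed by joint flux
    balance analysis, the attainable SCFA production is computed by a
    growth-constrained flux variability step, and minimal species subsets are
    found by sequential deletion followed by a mixed-integer linear program
    over a binary membership vector.  Includes a synthetic cross-feeding
    community generator with an exhaustive brute-force oracle, readers and
    writers for COBRA JSON and SBML L3 (fbc) models and diet tables, and a
    built-in dense bounded-variable simplex and branch-and-bound solver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
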