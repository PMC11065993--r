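Package: adgscan
Title: Regulatory-Motif-Guided Discovery of Anti-Defense Genes in
    Archaeal Virus Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers candidate anti-defense genes (ADGs, e.g.
    anti-CRISPR and antitoxin mimics) in annotated archaeal virus
    genomes from the conserved regulatory sequences that drive their
    expression immediately after infection. Extracts upstream regions
    of single and operon-lead genes, learns a per-genome regulatory
    motif by deterministic ZOOPS expectation-maximization, attaches
    exact position-weight-matrix p-values by dynamic programming over
    the score distribution, verifies a strong archaeal promoter core
    (purine-rich BRE followed by a TTTAWATA TATA-box), applies
    dual-criteria ADG calling with an audit trail of low-probability
    rules, clusters ADG proteins into families and computes per-family
    motif prevalence. Includes a ground-truth synthetic genome
    simulator so the whole pipeline is testable without downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
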