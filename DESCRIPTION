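Package: mpingr
Title: Short-Read Inventory of the mPing/Ping/Pong Transposable-Element Family
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for characterizing the rice mPing/Ping/Pong family of
    miniature inverted-repeat transposable elements (MITEs) and their
    autonomous partners from paired-end short reads. Includes a synthetic-data
    generator (genomes with known element insertions, nested insertions and
    paired-end libraries), a seed-and-extend read placement engine with
    per-position pileup profiles, non-reference insertion discovery with
    element discrimination via diagnostic internal regions, window read-depth
    copy-number estimation with one-sample t-tests, pseudogenome junction-read
    detection of the nested Ping16A_Stow structure, +16 G/A variant genotyping
    with shared-allele resolution, sequence-similarity graph classification of
    mPing subtypes, and cohort-level statistics (method correlation, rank-sum
    association, one-way ANOVA with Tukey HSD, and yeast transposition-rate
    arithmetic).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
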