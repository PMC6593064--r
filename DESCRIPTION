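Package: seedshift
Title: Allele-Specific miRNA Target-Site Analysis for 3'-UTR SNPs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for single-nucleotide polymorphisms located in
    microRNA binding sites of 3' untranslated regions. Provides case-control
    genotype and allele association testing (Hardy-Weinberg equilibrium,
    odds ratios with Woolf confidence intervals, Pearson chi-square and
    Fisher exact tests), canonical seed-match scanning with per-allele site
    classification, a three-state nearest-neighbor thermodynamic model of
    miRNA-target binding (minimum free energy folding, constrained folding
    with the site held open, and duplex hybridization), qPCR relative
    expression analysis (2^-dCt), and seeded synthetic-data generators that
    emulate the statistical structure of a miRNA-site SNP study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
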