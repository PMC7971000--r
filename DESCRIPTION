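Package: dosecomp
Title: Dosage-Compensation Analysis for Young Plant Sex Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to assess dosage compensation on young sex chromosomes
    from bulk RNA-Seq expression summaries. Implements outgroup-calibrated
    comparison of sex-linked versus autosomal expression, diagnostic-SNP
    allele-specific quantification of X and Y alleles in the heterogametic
    sex with trimmed-mean-of-M-values library normalization, ratio-based
    per-gene compensation classification stratified by evolutionary
    stratum, and a synthetic-data generator with ground truth that emulates
    a male/female multi-tissue study design with a monoecious outgroup.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
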