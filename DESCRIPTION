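Package: haplodose
Title: Haplotype-Based Noninvasive Prenatal Diagnosis from Maternal Plasma cfDNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Noninvasive prenatal diagnosis of monogenic disorders and
    chromosomal abnormalities from targeted SNP sequencing of maternal
    plasma cell-free DNA. Implements relative-haplotype-dosage fetal
    haplotyping with two-state hidden Markov models (Viterbi decoding,
    forward-backward posteriors, region log-odds), proband- and
    relative-assisted parental haplotype phasing, SNP-based fetal-fraction
    and sequencing-error estimation with QC gating, genome-wide SNP panel
    design (allele-frequency/GC/mappability filters, systematic 25-kb
    sampling, gene-region density boosting), and an aneuploidy and
    microdeletion/microduplication screening arm (GC LOESS normalization,
    PCA correction, chromosome-proportion Z scores, X/Y logic with the R
    value, circular binary segmentation with bootstrap confidence). A
    family simulator generates parental haplotypes, map-driven meioses,
    plasma allele depths and binned read counts with known truth so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
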