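Package: lethalmapr
Title: Mapping and Characterisation of Recessive Lethal Haplotypes in Livestock
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and characterising recessive lethal variants in
    pedigreed livestock populations from SNP-array and pedigree data: expected
    genetic contribution of ancestors to case and control groups, case/control
    sliding-haplotype homozygosity mapping with exact tests and Bonferroni
    thresholds, staged candidate-variant filtering against control genome
    panels, mating-type mortality contrasts with a closed-form expected
    mortality increase under complete penetrance, mixed-linear-model tests of
    heterozygote effects on quantitative traits with a genomic relationship
    matrix, Benjamini-Hochberg multiple-testing control, in-silico splicing
    consequence analysis (cryptic exons, premature termination codons,
    nonsense-mediated decay), and a forward-in-time pedigree/genotype simulator
    that reproduces the data structure these analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
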