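Package: rankqtl
Title: eQTL Mapping with Adaptive Linear Rank Tests and Pedigree
    Decorrelation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Expression quantitative trait locus (eQTL) mapping for
    pedigreed populations with non-normal expression data. Expression
    values are first de-correlated with a per-transcript sire-dam animal
    model (REML variance components against the pedigree numerator
    relationship matrix); genotype-expression association is then tested
    with a two-stage adaptive linear rank test that chooses among six
    k-sample rank tests (Kruskal-Wallis, median, long tails, short
    tails, right and left skewness) from label-blind selector statistics
    for skewness and tail weight. Includes Benjamini-Hochberg control of
    the genome-wide false discovery rate, cis/trans classification of
    associations, genotype quality control (missingness, minor allele
    frequency, Mendelian consistency), readers and writers for
    PLINK-text and VCF genotypes, and a simulator for an F2 cross
    (gamete dropping with Haldane recombination, polygenic covariance,
    planted cis/trans effects, configurable residual distributions) that
    provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
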