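Package: duogwas
Title: Genome-Wide Tests of Maternal Genetic Effects and Mother-Child
    Genotype Interaction in Case-Control Duos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide screening of maternal genetic main
    effects and maternal-offspring (transgenerational) genotype
    interaction in case-control mother-child pair ("duo") data.
    Implements stratified Cochran-Mantel-Haenszel association scans with
    empirical identity-by-state clustering and genomic-inflation-guided
    selection of the stratum count, three binary mother-child genotype
    classifiers (offspring-heterozygous, maternal-heterozygous and
    difference models), a multinomial maximum-likelihood model of duo
    genotype risk with nested likelihood-ratio tests, family-based
    (trio) replication analogues with random-effects meta-analysis,
    duo-aware quality control, and a synthetic genotype generator for
    structured case-control duo and affected-trio datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
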