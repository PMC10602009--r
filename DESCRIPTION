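Package: loxcross
Title: Cross Enumeration and Breeding Simulation for Cre-Lox Dual-Marker Transgenes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact Mendelian cross enumeration and seeded stochastic breeding
    simulation for diploid organisms carrying dual-marker Cre-Lox transgene
    constructs. Models germline Cre excision (with configurable bias and
    completeness), two-point meiotic linkage on a chromosome, independent
    assortment, and X-linked inheritance. Provides the estimators used to
    analyse progeny score tables from such breeding schemes: two-point genetic
    linkage in centimorgan, Cre excision bias, insert-number and
    homozygous-viability classification, and one-sample t-tests of observed
    versus theoretical segregation ratios. Includes orchestration of the full
    single-transgene and double-transgene homozygosing mating procedures with
    phenotype-only selection and abort logic, and a synthetic-data generator
    producing reproducible multi-subline, multi-generation score tables with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
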