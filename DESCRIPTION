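Package: hapforge
Title: Variant Discovery and Population-Genetics Filtering for Inbred Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Discovery and quality control of sequence variants in panels of
    (mostly) inbred lines genotyped by low-coverage whole-genome sequencing.
    Implements per-taxon six-allele depth extraction with a one-byte storage
    codec, likelihood genotype calling, a hybrid chi-square / Monte-Carlo
    Fisher segregation test on allelic depth tables, identity-by-descent
    genotype filtering against a trusted anchor map, a local linkage
    disequilibrium filter, a minor-allele read-depth filter, LD-KNN genotype
    imputation with self-imputation accuracy statistics, annotated VCF
    output, and a synthetic inbred-cohort simulator with ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
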