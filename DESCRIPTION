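Package: ifsgp
Title: Incremental Feature Selection for Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic prediction with GWAS-ranked incremental feature
    selection (IFS). Markers are ranked by single-SNP linear-regression
    association on training data only, random-forest models are trained on
    growing marker subsets under repeated cross-validation, the resulting
    accuracy curve is smoothed with Friedman's variable-span super smoother
    to locate the optimal marker count, and the selected model is compared
    with the all-marker baseline on a held-out partition. Includes a
    bit-exact reader/writer for PLINK 1.x binary genotype files and a
    synthetic genotype-phenotype simulator with additive and epistatic
    architectures at a target heritability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ranger,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
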