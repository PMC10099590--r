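Package: ssgblup
Title: Single-Step Genomic BLUP with SNP and Haplotype Relationship Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Pedigree and single-step genomic evaluation for sheep breeding
    data. Builds numerator relationship matrices and their sparse inverses
    with inbreeding, VanRaden genomic relationship matrices from SNP or
    haplotype-block pseudo-SNP genotypes, and blended H-inverse systems.
    Assembles and solves animal-model mixed-model equations (additive,
    repeatability, and maternal models) with known variance components,
    returning breeding values, prediction error variances and theoretical
    accuracies. Includes contemporary-group phenotype preparation, genotype
    quality control, LD-based haplotype blocking, forward (whole/partial)
    validation by the linear-regression method, and a gene-dropping
    population simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
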