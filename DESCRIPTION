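Package: TP53state
Title: Allelic-State Classification of TP53 Mutations in Myeloid Neoplasia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Resolves the allelic configuration of somatic TP53 mutations in
    myeloid neoplasms from routinely available bulk sequencing data. Implements
    the traditional single/double-hit classification and a three-group
    allelic-state algorithm (obligatory biallelic, probable biallelic, probable
    monoallelic) driven by combined variant allele frequency arithmetic, a
    survival-concordance cross-validation procedure that selects the VAF cutoff
    separating probable monoallelic from probable biallelic cases, a clonal
    architecture simulator producing bulk cohorts and single-cell genotype
    matrices with known ground truth, and single-cell analyses that quantify
    biallelic cell fractions and discriminate compound-heterozygous clones from
    subclonal mosaicism.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    survival,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
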