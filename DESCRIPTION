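Package: matescan
Title: Quantitative Genetics and Pooled-Sequencing Mapping of Male Mating
    Success
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting the genetic basis of variation in male
    mating success against a discriminating female tester, modelled on
    inbred-panel and advanced-intercross designs in Drosophila
    melanogaster.  Provides replicate-level mating-assay quantitative
    genetics (REML variance components, broad-sense heritability, line-mean
    trait correlations, inversion karyotype effects, Fisher exact
    contrasts), inversion- and Wolbachia-adjusted mixed-model genome-wide
    association with a genomic relationship matrix, pooled-sequencing
    extreme-QTL Z scans with an all-pairs rule for unpaired
    evolve-and-resequence pools, selection-response regression, and a
    forward simulator of the breeding, assay, truncation-selection and
    pool-sequencing designs that makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
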