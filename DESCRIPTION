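Package: annofine
Title: Annotation-Aware Statistical Fine-Mapping of GWAS Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative statistical fine-mapping of trait-associated loci
    from GWAS summary statistics. Combines association Z-scores, linkage
    disequilibrium, and binary functional annotations under a multivariate
    normal likelihood that allows multiple causal variants per locus, with
    an empirical-Bayes logistic prior on causal status whose annotation
    coefficients are estimated across loci by an EM algorithm. Provides
    per-SNP posterior probabilities of causality, credible sets, annotation
    enrichment estimates with likelihood-ratio tests and bootstrap standard
    errors, baseline prioritizers for benchmarking, a benefit-to-cost
    utility optimizer for follow-up selection, and a simulator of synthetic
    fine-mapping data sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
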