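Package: exomeCarrier
Title: Carrier-Rate Epidemiology of Recessive Disorders from Population
    Exome Cohorts
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates per-population carrier rates of recessive-disease
    mutations from population exome cohorts. Matches observed variants
    against a curated disease-mutation panel, aggregates alternate-allele
    counts (AC/AN) per population from VCF genotypes with configurable
    site-level quality filters, converts allele counts to carrier-rate
    estimates under the rare-allele Hardy-Weinberg approximation, tests
    concordance of estimates between cohorts (pooled two-proportion z-test)
    and against external clinical prevalence (goodness-of-fit chi-square),
    and models mutation detection probability as a function of cohort size,
    carrier rate and sequencing error, with a Monte-Carlo twin. Includes a
    seeded synthetic-cohort generator (VCF plus sample manifest with known
    truth) so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    GenomeInfoDb,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
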