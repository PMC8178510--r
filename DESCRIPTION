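Package: eqtlmr
Title: Cis-eQTL Mapping and Mendelian Randomization Screening of
    MicroRNA Target Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A screening pipeline that maps GWAS risk loci onto microRNA
    expression by covariate-adjusted cis-eQTL regression, identifies
    downstream mRNA targets by single-instrument Mendelian randomization
    (Wald ratio / two-stage least squares), and filters candidates through
    differential-expression, survival and clinicopathological association
    stages. Includes genotype quality control (imputation info score,
    minor allele frequency, per-call posterior probability,
    Hardy-Weinberg equilibrium, linkage-disequilibrium tag expansion,
    principal-component ancestry assignment), expression preprocessing
    (log2(RPM+1) transform, outlier masking, missingness filters, copy
    number and CpG methylation categorization), Benjamini-Hochberg FDR
    screening, Cox proportional-hazards and Kaplan-Meier log-rank survival
    screens, odds ratios from 2x2 clinicopathological tables, and a seeded
    synthetic-cohort generator that emulates the statistical structure the
    analysis assumes so every stage is testable without controlled-access
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
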