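Package: longage
Title: Longitudinal Two-Timepoint Analysis of Gene Expression, Splicing, and
    Their Genetic Regulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical machinery for paired two-timepoint (e.g. ages 70 and
    80) RNA-seq cohorts: expression filtering and normalization, surrogate
    variable correction with permutation-based factor counting, paired
    linear mixed models for differential expression with Satterthwaite
    degrees of freedom and Storey q-values, age-trajectory outlier
    detection, cis-eQTL/sQTL mapping with Simes gene-level p-values,
    hierarchical and two-step replication FDR, cis-GREML heritability and
    cross-age genetic correlation with a logit-scale beta regression trend
    model, latent-phase beta-binomial (mixed) models for allele-specific
    expression, Dirichlet-multinomial differential splicing, and a
    synthetic-cohort generator that emulates all required inputs so every
    stage is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    DESeq2,
    sva,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest,
    vcfR,
    optparse
Config/testthat/edition: 3
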