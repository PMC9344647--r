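Package: endomap
Title: Genetic Variants Enriched by Brain-Imaging Endophenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies disease-associated genetic variants enriched by
    brain-imaging endophenotypes.  Regional imaging quantitative traits are
    regressed on diagnosis and on each SNP (adjusting for covariates) to
    produce brain-wide significance maps, and each SNP is then scored by the
    Pearson correlation between its genetic-effect map and the
    diagnostic-effect map, with Bonferroni control over the SNP family.
    Includes genotype quality control (call rate, minor allele frequency,
    Hardy-Weinberg exact test), comparator analyses (covariate-adjusted
    logistic GWAS, Pearson and partial correlation of SNP with diagnosis), a
    random-SNP-set resampling experiment, and a synthetic cohort generator
    with a planted SNP -> imaging trait -> diagnosis mediation structure so
    the whole pipeline can be exercised without restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
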