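Package: snpmon
Title: SNP Panel Design and Non-Invasive Genetic Monitoring of Wolf Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing reduced SNP panels and running annual
    non-invasive genetic-monitoring workflows for wild canid populations.
    Covers marker selection from dense reference genotypes (call-rate
    filters, windowed LD pruning, Hardy-Weinberg exact tests, per-locus
    FST, category-specific selection rules), replicate quality control and
    consensus genotyping, likelihood-based species assignment with
    leave-one-out validation, genetic sexing from X-heterozygosity and a
    Y presence marker, individual identification by pairwise allele
    matching, probability-of-identity statistics (PID and PIDsib),
    Mendelian parentage with an explicit genotyping-error allowance, and
    pedigree inbreeding coefficients. A seeded synthetic-data generator
    emulates multi-species reference panels, material-specific genotyping
    error, duplicated scat samples, urine cross-contamination and inbred
    pedigrees so the whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    igraph,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
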