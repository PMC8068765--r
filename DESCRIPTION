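Package: snvconcord
Title: Cross-Sample Concordance Benchmarking of Somatic SNV Calling Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates somatic single-nucleotide-variant calling pipelines
    (mapper x caller combinations) by cross-sample concordance when no ground
    truth exists. Variants detected in at least two independent samples of the
    same tumor are treated as validated; each pipeline is scored by precision,
    recall and F1 against this validated set, pipelines are compared by
    cosine/Jaccard/Pearson similarity with hierarchical clustering, and every
    possible union of pipelines is enumerated and scored to find complementary
    combinations. Includes a truth-known call-level simulator of multi-sample
    tumor studies (clonal structure, tumor purity, per-pipeline detection
    behavior) so the whole analysis is testable end to end, plus truth-based
    scoring to audit the validation statistic itself.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    vcfR,
    ape,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
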