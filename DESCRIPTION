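Package: revscreen
Title: Signature-Reversal Drug Repositioning with Synthetic Benchmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for transcriptome-signature-reversal drug repositioning.
    Builds tumour-versus-normal disease signatures with an empirical-Bayes
    moderated t-test, scores drug perturbation profiles for reversal potency
    with a connectivity-style weighted Kolmogorov-Smirnov statistic (RGES)
    summarized across cell lines, doses and times (sRGES), applies
    candidate-selection and consensus over-representation rules, matches
    model cell lines by transcriptional similarity, computes dose-response
    sensitivity metrics, correlates candidate biomarker copy number and
    expression with drug sensitivity, and filters copy-number segments into
    gene-level GISTIC-style calls. A synthetic-data module with planted
    differential expression, planted reversal drugs and a planted
    copy-number/sensitivity biomarker link makes every stage verifiable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
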