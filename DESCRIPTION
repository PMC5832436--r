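Package: sgzr
Title: Somatic-Germline-Zygosity Classification of Variants from Tumor-Only Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies sequence variants from tumor-only deep sequencing as
    somatic, germline, or subclonal somatic, and determines their zygosity in
    the tumor (homozygous, heterozygous, not in tumor), without a
    patient-matched normal. A genome-wide allele-specific copy-number model
    (tumor purity, ploidy, per-segment copy number and minor-allele count) is
    fitted to median-normalized coverage log-ratios and heterozygous-SNP
    minor allele frequencies by circular binary segmentation, grid search,
    and Markov chain Monte Carlo; each variant's observed allele frequency is
    then compared against model-derived germline and somatic expectations
    with exact two-tailed binomial tests. Includes a synthetic-specimen
    simulator with known truth, a cohort-level Bayesian aggregator for
    recurrent variants, broom-style tidiers, and ggplot2 visualisations.
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
    readr,
    stringr,
    ggplot2,
    stats,
    utils,
    Rcpp,
    yaml,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
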