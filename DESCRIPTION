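Package: twostepseq
Title: Two-Step Multiplexed RNA-Seq Screening, Re-Pooling Optimization and
    Depth Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and evaluating two-step multiplexed RNA-seq
    screens: a shallow, highly multiplexed screening run over many treatment
    conditions followed by re-pooled deep sequencing of the most responsive
    conditions. Implements digital read-concentration re-pooling volumes that
    equalize cumulative per-library depth, a negative-binomial Wald
    differential-expression engine with a mean-dispersion trend and
    Benjamini-Hochberg FDR control, the FPKM / covariate-regression / quantile
    normalization / trimmed-mean centering chain with sample correlation
    clustering, binomial downsampling of count matrices to emulate higher
    multiplexing, and a synthetic-data generator emulating uneven flow-cell
    read allocation and NB counts with treatment effects and GC/length bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
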