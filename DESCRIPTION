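Package: orenhancer
Title: Conservation and Regulatory Analysis of Odorant-Receptor Enhancer Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising long-range cis-regulatory elements of
    odorant-receptor (OR) gene clusters. Implements cross-species enhancer
    conservation scoring from UCSC pairwise whole-genome alignments (coverage,
    identity and the conservation index), VISTA-style sliding-window percent
    identity profiling with conserved-segment calling, degenerate (IUPAC) motif
    scanning and log-odds profile search for enhancer core regions,
    percentile-shift normalised differential expression of a clustered gene
    family with fold-change classification and distance-decay correlation, and
    the summary-statistic hypothesis tests used for per-genotype cell counts.
    A synthetic-data generator produces every input with known ground truth so
    the full pipeline is testable without genome downloads.
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
    stringr,
    ggplot2,
    jsonlite,
    yaml,
    withr,
    generics,
    stats,
    utils,
    Biostrings
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
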