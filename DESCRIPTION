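Package: patternEffect
Title: Expected Pattern Effects for Multi-Task Sequence-Activity Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains ensembles of multi-task convolutional neural networks that
    predict class-specific regulatory activity (chromatin accessibility or
    transcription-factor binding) from fixed-length DNA windows, and interprets
    them by in-silico pattern insertion. The Expected Pattern Effect (EPE) is
    the mean ratio of class predictions on background sequences with versus
    without an inserted pattern (a motif consensus, a sampled site, or a motif
    pair at a fixed spacing); the Differential Expected Pattern Effect (DEPE)
    contrasts two classes through per-background differences of log2 prediction
    ratios. Both carry a normalized Wilcoxon signed-rank statistic and p-value,
    with Bonferroni or Benjamini-Hochberg correction across motif panels.
    Includes readers for BED, FASTA, HOCOMOCO and HOMER motif formats,
    chromosome-held-out data splitting, a synthetic-grammar sequence generator
    for benchmarking, spacing scans, per-base differential saliency, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
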