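Package: chromactivity
Title: Differential Chromatin Accessibility and Transcription Factor Motif Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for inferring transcription factor
    activity from ATAC-seq chromatin accessibility. Starting from accessible
    chromatin sites (ACS) and per-sample Tn5 fragment intervals, the package
    counts transposase insertions, tests each site for differential
    accessibility between conditions with a TMM-normalised negative binomial
    exact test, scans site sequences against JASPAR-format position weight
    matrices with exact dynamic-programming match p-values, summarises motifs
    by preranked set enrichment (weighted Kolmogorov-Smirnov statistic with a
    permutation null) and by elastic-net regression of accessibility
    fold-changes on the motif match matrix, and finally links sites to nearby
    genes to call enhancer- or repressor-like regulatory roles. A synthetic
    data generator with known planted ground truth makes the whole chain
    testable without any external download.
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
    tools,
    utils,
    yaml
Suggests:
    edgeR,
    fgsea,
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
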