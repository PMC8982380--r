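Package: acvu
Title: Quantification and RNAi Screen Analysis for Anchor-Cell Fate Reporters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying per-nucleus GFP reporter fluorescence in
    two-channel confocal z-stacks of the C. elegans somatic gonad primordium,
    naming the four anchor-cell-competent cells (alpha1, alpha2, beta1, beta2),
    classifying cells against an "AC-like" fluorescence threshold, and calling
    hits in penetrance-based RNAi screens with negative and positive control
    quality gates. Includes a synthetic image and screen-dataset generator with
    known ground truth for end-to-end validation, and the nonparametric
    statistics used throughout (exact Mann-Whitney U, Kruskal-Wallis with
    Dunn's post hoc comparisons, Fisher's exact test).
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
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
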