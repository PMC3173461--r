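Package: pistatus
Title: Diagnostic Gene Expression Markers of Plant Phosphate Status
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovery and application of diagnostic gene-expression markers of
    plant inorganic-phosphate (Pi) status from two-colour time-course
    microarrays. Implements Lowess intensity-dependent normalization with a
    control-channel floor, per-gene median scaling, the three-rule gene
    pre-filter, two-factor ANOVA differential expression with
    Benjamini-Hochberg FDR control, hierarchical clustering of response
    profiles with threshold symbolization, hypergeometric term
    overrepresentation, Golub signal-to-noise feature selection, kernel
    support-vector-machine class prediction emitting per-sample margin values
    (positive = Pi deficient), ortholog-mapped transfer of classifiers across
    platforms, and a seeded synthetic-data generator emulating a full dye-swap
    time-course design with planted response patterns plus labelled field test
    sets.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
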