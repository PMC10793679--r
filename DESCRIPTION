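Package: pouchtrack
Title: Longitudinal Microbiota Analysis for Fecal Microbiota Transplantation Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal 16S rRNA gene amplicon count
    tables from fecal microbiota transplantation (FMT) trials, built around
    chronic pouchitis cohort designs. Implements donor-engraftment
    quantification via donor-only OTU set classification, averaged Bray-Curtis
    dissimilarity-to-donor trajectories with post-relapse sample exclusion,
    inverse Simpson diversity, principal coordinates analysis, one-way
    PERMANOVA and multivariate dispersion homogeneity tests, nonparametric
    group comparisons with Benjamini-Hochberg false discovery rate control,
    and a synthetic FMT-cohort generator that provides ground truth for every
    analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape,
    withr
Config/testthat/edition: 3
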