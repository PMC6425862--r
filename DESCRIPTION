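Package: dielshift
Title: Cross-Species Diel Expression Rescheduling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing diel (24-hour) time-course gene expression
    between species with different photosynthetic modes. Classifies each gene
    as dawn- or dusk-enriched using window sums of normalized expression
    pseudo-counts, a right-tailed Fisher exact test, and Benjamini-Hochberg
    false discovery rate control per species and window; combines per-species
    phase calls with Spearman rank correlations across ortholog groups to
    detect rescheduled (anti-phase) expression of a CAM-species gene relative
    to two C3-species orthologs. Includes cubic-spline resampling of coarser
    sampling grids to a common 2-hour grid, keyword/E-value filtering of
    literature-homology hit records, a synthetic diel study generator with
    planted ground truth, and a single-config pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
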