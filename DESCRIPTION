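Package: plaquetools
Title: Amyloid Plaque Segmentation, Immunoassay Calibration and Rank
    Statistics for Brightfield IHC Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative pipeline for longitudinal mouse-model amyloid
    histopathology and biochemistry. Separates DAB and hematoxylin staining
    in brightfield immunohistochemistry images via Beer-Lambert optical
    density unmixing, segments amyloid plaques by seeded region growing
    from dark-stain cores with a five-rule object filter, and reports
    per-region plaque burden. Companion modules fit four-parameter logistic
    immunoassay standard curves with LOD/LLOQ determination, and provide
    tie-corrected Kruskal-Wallis with Dunn's post-hoc comparisons and exact
    small-sample permutation Spearman correlation. A synthetic-data module
    renders histology sections, assay plates and grouped measurements with
    known ground truth for validation.
License: MIT
Encoding: UTF-8
Imports:
    tools,
    Rcpp,
    jsonlite,
    minpack.lm,
    png,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
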