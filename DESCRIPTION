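Package: pdrim
Title: Perihematomal Diffusion-Restriction Rim Analysis for Hyperacute
    Intracerebral Hemorrhage MRI
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and quantification of the perihematomal rim of
    restricted diffusion (PDR) in hyperacute intracerebral hemorrhage from
    co-registered multimodal MRI (FLAIR, b1000 diffusion-weighted, ADC and
    T2*/SWI volumes). Provides a synthetic multimodal phantom and cohort
    generator with ground-truth compartment masks, integer-translation
    registration by normalized cross-correlation, automated hematoma and
    lesion segmentation with FLAIR-based clot-border refinement, contralateral
    mirror-region construction, the mirror-referenced ADC threshold rule for
    rim detection, ROI volumetry and quantile statistics with relative ADC,
    and the accompanying statistical battery (Pearson chi-squared, two-sided
    Fisher exact, Mann-Whitney U, Kruskal-Wallis, Pearson correlation and
    multivariate logistic regression) for cohort tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    foreign,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
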