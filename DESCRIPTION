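Package: focalstage
Title: Focal Amyloid PET Staging with Direct-Comparison Centiloid Scaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantification and staging of regional amyloid burden from
    florbetaben (FBB) and flutemetamol (FMM) PET. Aggregates volume-of-interest
    uptake into ten composite cortical and striatal regions, converts global
    SUVR to direct-comparison Centiloid (dcCL) units, derives per-region
    SUVR positivity cutoffs from a cognitively unimpaired reference sample by
    iterative Tukey-fence outlier removal, classifies participants into
    global/focal amyloid groups with focal and whole-brain subtypes, and
    provides the accompanying group-comparison statistics (ANCOVA with Tukey
    post hoc, Mann-Whitney, Jonckheere-Terpstra trend, bootstrap comparison of
    regional involvement frequencies, AIC-based grouping comparison). Includes
    a synthetic cohort generator so the full pipeline can be exercised and
    tested without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    emmeans,
    stats,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
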