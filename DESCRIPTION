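Package: connrecov
Title: Longitudinal Neural Connectivity Change and Neurobehavioral Recovery
    Analysis for Small Sensory-Training Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline linking a sensory-training intervention to
    changes in resting-state functional connectivity, white-matter structural
    connectivity, and neurobehavioral recovery in small two-arm disorders-of-
    consciousness cohorts. Covers motion scrubbing (framewise displacement and
    DVARS censoring), within- and between-network Fisher-z connectivity
    metrics, tract-mean fractional anisotropy extraction with tract-length
    standardized verification, partial-credit and many-facet Rasch person
    measurement, mixed-effects change indices with group-nested imputation,
    exact enumerated permutation tests with ordered p-values, Benjamini-
    Hochberg false-discovery-rate filtering, and change-change correlation
    discovery. A synthetic-cohort generator reproduces the statistical
    structure every stage assumes so the whole pipeline runs without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
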