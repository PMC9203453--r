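Package: lesioncast
Title: Estimating Stroke Lesion Occurrence in Brain Regions from
    Non-Imaging Clinical Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the presence of stroke lesions in brain
    atlas regions from non-imaging clinical test scores. Implements
    subject-level lesion occurrence and sparsity statistics, unsupervised
    stratification of patients on the (occurrence, sparsity) plane,
    classification of the resulting subsets from clinical features alone,
    region-wise logistic lesion models with nested cross-validation,
    resampling and AIC-based model selection, OR-logic transfer of
    predictions across atlas resolutions (AAL regions, lobes,
    hemispheres), the associated evaluation statistics, and a synthetic
    cohort generator for testing every stage without patient data.
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
    glmnet,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mclust,
    RNifti,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
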