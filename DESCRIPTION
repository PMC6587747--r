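Package: corehyb
Title: Metabolome-Based Core Hybrid Selection and Cross-Environment
    Trait Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts quantitative traits of F1 hybrids (thousand grain
    weight in rice) from parental untargeted metabolite profiles.
    Mid-parent metabolite abundances serve as predictors in partial
    least squares (PLS) regression; metabolic markers are screened by
    PLS discriminant analysis and variable importance in projection
    (VIP); representative "core" hybrids are chosen per population by
    interval sampling along the first principal component; and
    cross-environment training compositions are evaluated by the
    Pearson correlation between observed and predicted trait values.
    Includes a synthetic-data generator that emulates two metabolically
    distinct hybrid populations (a complete diallel and a CMS female x
    recombinant inbred line design) so the whole pipeline can be
    exercised and tested without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
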