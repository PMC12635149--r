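Package: antmimic
Title: Quantifying Batesian Color and Size Mimicry in Ants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for model-mimic phenotype matching from RGB color
    and cephalic-size measurements of ant workers. Provides square-root color
    transforms and per-body-part principal-component reduction, nested
    (nest-within-site) mixed-model trait comparisons with Holm-corrected pairwise
    contrasts, a syntopic-versus-allotopic Euclidean distance statistic with
    one-sided paired t-tests, stepwise Wilks'-lambda linear discriminant analysis
    with leave-one-out cross-validation and wild-card allocation of mimic
    individuals, per-site mean-color reconstruction, and a hierarchical
    synthetic-data generator emulating the specimen-table schema.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    stats,
    tools,
    utils,
    jsonlite
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
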