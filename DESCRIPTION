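Package: menokin
Title: Kinship Demography and Comparative Analysis of Menopause Evolution in Toothed Whales
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative life-history analysis of the evolution of
    menopause in odontocetes. Fits Bayesian Gompertz mortality models to
    published age-at-death samples while accounting for population growth,
    windowed sampling bias and age-estimation error; models ovarian corpora
    deposition to estimate reproductive cessation ages; builds Leslie matrices
    and kinship-demography projections to quantify grandmother years, mother
    years and mother-daughter reproductive overlap; runs phylogenetically
    controlled measurement-error regressions with an Ornstein-Uhlenbeck
    covariance kernel over bootstrap chronograms; and constructs counterfactual
    (ancestral and slow life history) demographies for menopausal species.
    Includes synthetic-data generators emulating the statistical structure of
    the underlying data so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
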