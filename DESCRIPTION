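Package: gravitherm
Title: Phylogenetic Analysis of Maternal Thermoregulation and the Evolution of Live Birth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Comparative phylogenetic toolkit for studying how gravid female
    squamates shift their body temperature toward embryonic thermal optima and
    how that behavioural plasticity relates to evolutionary transitions from
    egg laying to live birth. Implements heteroscedastic standardized mean
    differences (Hedges' g, SMDH) for gravid versus non-gravid body
    temperature, single- and multi-response Bayesian phylogenetic mixed models
    (Gaussian and binomial responses, phylogenetic random intercepts and
    slopes, measurement-error weighting, missing-response augmentation) fitted
    by Gibbs sampling, derivation of embryonic thermal optima from quadratic
    hatching-success curves, predictive-mean-matching multiple imputation,
    hidden-rate Markov models with marginal ancestral state reconstruction and
    AIC rate-category selection, node-level transition classification and
    thermal-mismatch tests, and a synthetic-data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
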