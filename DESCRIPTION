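Package: snailcline
Title: Urban Heat Island Clines in Snail Shell Colour Polymorphism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for citizen-science observations of shell colour
    and banding polymorphism in the grove snail (Cepaea nemoralis) along urban
    heat island and climate gradients. Provides banding-code parsing and record
    filtering, habitat assignment from a categorical land-use grid, a
    maximum-likelihood baseline-category multinomial logit fitted by Newton
    iteration with Wald inference, morph darkness scoring with thermal-sum
    binning and a log-curve fit, Wilson score intervals and urban-heat-island
    proportion curves, residual spatial autocorrelation diagnostics (global
    Moran's I with analytical null moments, distance-class correlograms) and a
    penalized-spline smoothed multinomial refit, exact multinomial
    goodness-of-fit tests, Kaplan-Meier shell-discovery analyses, and a
    synthetic-data generator that emulates a Netherlands-like landscape and
    observation process so the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere,
    survival,
    splines,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nnet,
    ape,
    withr
Config/testthat/edition: 3
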