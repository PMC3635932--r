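Package: crrsim
Title: Precision and Power of Harm-Rate Monitoring by Clinical Record Review
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo assessment of the precision and statistical power of
    clinical record review (CRR) designs for estimating and monitoring rates of
    patient harm in general practice. Simulates harm-incident counts from a
    Poisson-lognormal model with patient- and practice-level random effects
    parameterised by median rate ratios, estimates harm rates with a log-linear
    Poisson rate model, aggregates replicates into estimation error, power,
    bias and coverage, and provides a closed-form planning calculator linking
    expected harm-incident counts to review design parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
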