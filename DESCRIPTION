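Package: mglca
Title: Multigroup Latent Class Models for Binary Musculoskeletal Pain Indicators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Latent class analysis of binary symptom indicators as finite
    mixtures of independent Bernoulli items, fitted by multi-start EM with a
    maximum-absolute-deviation convergence criterion and missing-at-random
    marginalization. Provides G-squared and Pearson goodness-of-fit statistics
    on response-pattern tables, G-squared-based AIC/BIC class enumeration with
    a five-percent-decrease rule, posterior class assignment by Bayes' theorem,
    multigroup models with group-specific membership probabilities and a
    chi-square difference test of measurement invariance of the item-response
    probabilities, prevalence descriptives with Wilson intervals and compact
    letter displays, and a seeded synthetic-data generator parameterized by
    packaged estimates from a published study of multisite musculoskeletal
    pain in 1611 schoolchildren.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
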