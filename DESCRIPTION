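Package: degdom
Title: Degree-of-Dominance Inference for Case-Control Genetic Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the mode of inheritance of a bi-allelic variant from a
    3x2 case-control genotype table using two orthogonal genetic contrasts
    (additive and co-dominant), the degree-of-dominance index h, and a
    one-sided k-test for over- and under-dominance. Decomposes the genotype
    deviance of the grouped binomial logit model across the two contrasts,
    quantifies Hardy-Weinberg disequilibrium in controls and the bias it
    induces in h, and provides Monte-Carlo machinery: a one-locus selection
    cohort simulator with known true dominance for validating h, a power
    simulator for the co-dominant contrast under HWE-conforming controls,
    and batch classification of many studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
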