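Package: bfdesign
Title: Bayes-Factor-Optimal Group Sizes for Studies with Ordered Group Means
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Plans group sizes for studies that compare K group means under an
    order-constrained (informative) hypothesis H1: mu1 < mu2 < ... < muK tested
    against its complement with an approximated adjusted fractional Bayes
    factor. Given a priori group means, within-group variances, per-subject
    costs and a fixed budget (or a fixed total sample size), the package
    enumerates the integer design space and finds the allocation that
    maximizes the Bayes factor, alongside the classical equal-size, A-optimal
    and D-optimal allocations from the significance-testing framework.
    Ordering probabilities are evaluated deterministically through
    multivariate-normal orthant probabilities of successive differences, with
    a seeded Monte Carlo backend as an alternative. Parameter sweeps over one
    group's cost, mean or variance support sensitivity analyses, and a small
    command-line interface drives the same computations from config files.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mvtnorm,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
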