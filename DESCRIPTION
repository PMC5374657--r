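Package: cqvalue
Title: Conservative Adjustment of q-Values for False Discovery Rate Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates false discovery rates in genome-wide expression
    studies via q-values computed from a pooled permutation null
    distribution, and provides a conservative adjustment: upper confidence
    limits on the q-value built from one-sided order-statistic
    (incomplete-beta) bounds on the permutation p-value and on the
    empirical exceedance fraction, combined under a multiplicative
    mis-coverage budget so that the adjusted q-value exceeds the
    theoretical q-value with prescribed probability. Includes a
    two-group permutation engine for absolute t statistics, Storey-type
    and fixed conservative estimators of the true-null proportion, a
    simulation harness with a theoretically exact FDR oracle based on
    central and noncentral t distributions, and TSV readers/writers plus
    a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
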