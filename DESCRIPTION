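Package: heblrt
Title: Likelihood Ratio Tests for Homeolog Expression Bias from RNA-Seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects homeolog expression bias (HEB) and changes in homeolog
    expression bias between conditions (delta-HEB) from replicated RNA-seq
    read counts of homeologous gene pairs in polyploids. Counts are modelled
    with a negative binomial distribution whose mean is an expression level
    times gene length and sequencing depth; per-replicate aggregation
    (overdispersion) parameters are estimated by least-squares fitting of the
    negative binomial mean-variance relation after depth rescaling. Maximum
    likelihood estimates are obtained by Newton root-finding on transformed
    score equations, and nested hypotheses are compared with chi-squared
    likelihood ratio tests with Benjamini-Hochberg correction across pairs.
    Includes a synthetic-count simulator, power analysis over replicate
    numbers and fold changes, naive t/z comparator tests on log ratios, and
    full/partial ROC benchmarking.
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
    withr
Config/testthat/edition: 3
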