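Package: changelink
Title: Linking Average-Based and Individual-Based Change in Pre-Post Designs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating pre-post change at the group and at the
    individual level, and for studying the relation between the two.
    Implements average-based change statistics (the standardized mean
    pre-post difference d and Hays' omega-squared for the group-by-occasion
    interaction), individual-based change statistics (the standardized
    individual difference SID, the reliable change index RCI, and the
    percentage or net percentage of reliable individual changes), a
    Pearson-distribution-system generator of correlated non-normal pre/post
    scores, a Monte-Carlo study runner over a factorial grid of effect
    sizes, sample sizes, pre-post correlations and distribution shapes, and
    link-function fits (linear, quadratic, cubic, logistic) that convert an
    average-based effect size into an expected percentage of reliable
    individual changes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
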