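Package: gwmed
Title: Genome-Wide Multimediator Mediation Testing with the Composite Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Hypothesis testing for mediation effects across thousands of
    causal graphs, each linking an exposure to an outcome through a group of
    correlated mediators. Path-level mediation p-values are computed under the
    composite null (Sobel, joint-significance, and the composite test based on
    the normal product distribution with genome-wide variance estimates), and
    integrated into graph-level tests with Berk-Jones and generalized
    Berk-Jones statistics via a decorrelation approach, a multivariate
    approach, and a Cauchy-combination hybrid. Includes a simulation engine
    for genome-scale calibration and power studies, false discovery rate
    control, and delimited-file input/output with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
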