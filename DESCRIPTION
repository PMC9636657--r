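Package: callusopt
Title: Surrogate-Assisted Optimization of Plant Callus Induction Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing in vitro callus induction over a discrete
    factorial design of culture conditions (plant growth regulator treatment,
    explant type, Murashige-Skoog medium strength, sampling day). Provides a
    seeded generator for factorial replicate data, multilayer perceptron and
    radial basis function network surrogates for callus induction percentage
    and induction speed, RMSE/R-squared evaluation with leave-one-variable-out
    sensitivity ranking (VSE/VSR), and a discrete single-point-crossover
    genetic algorithm with single-objective and non-dominated multi-objective
    modes, including an exhaustive-enumeration oracle over the 192-point
    design space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet,
    optparse
Config/testthat/edition: 3
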