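Package: symobs
Title: Symbolic Observability Analysis of Rational Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the nonlinear observability of rational
    ordinary-differential-equation models of reaction networks without any
    numerical integration or computer-algebra determinant. Each Jacobian
    entry is abstracted to one of four symbols (absent, linear, polynomial
    nonlinear, rational), a symbolic observability matrix is assembled from
    Lie-derivative rows for any measurement configuration, and a symbolic
    observability coefficient in [0, 1] is computed from a sign-free
    determinant summary. Two graph-strength criteria preselect minimal
    sensor sets, and search utilities enumerate, evaluate and rank
    reconstruction configurations. Ships three classic fixtures (a 5D
    circadian oscillator, a 9D Rayleigh-Benard truncation and a 13D cell
    cycle model) plus a seeded generator of synthetic systems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
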