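Package: myofractal
Title: Fractal Models of Coordinated Myogenesis Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two fractal models of coordinated early-myogenesis gene
    expression in chick embryos, built on signed qPCR fold-change panels.
    Model 1 fits rank-exponential curves |FC-1| = a + K*exp(N) to
    magnitude-ranked fold changes, yielding breed slope coefficients K,
    log-log fractal dimensions D over selectable rank windows, and the
    integral indices MGEI = K(breast)/K(thigh) and
    MGEFDI = D(breast)/D(thigh). Model 2 builds fractal portraits of
    signed log2-transformed expression, detects "expression fractals"
    (gene sets collinear in the portrait, equivalently arithmetic
    progressions of shifted log expression), and computes the
    bioconsolidation index Ind = sqrt(NB*NT)/NG. Includes the printed
    eight-breed chicken panel as a bundled fixture, phenotype statistics
    (growth rates, NO oxidation, normality-gated Spearman correlations,
    category ANOVA), seeded synthetic-panel generators for every model
    structure, and a command-line pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
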