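Package: boolfba
Title: Hybrid Boolean-Regulatory and Constraint-Based Metabolic Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Couples asynchronous Boolean regulatory models with
    constraint-based metabolic networks to study metabolic reprogramming of
    stromal cells, in particular the reverse Warburg effect in breast
    cancer-associated fibroblasts. Parses SBML-qual logical models, fixes
    cell- and disease-specific initial conditions from differential-expression
    contrasts plus curated literature, computes value propagation and minimal
    trap spaces, derives zero-flux constraints on a metabolic model from the
    asymptotic state of metabolic components, runs flux balance analysis with
    an ATP-production objective, reports glycolytic/oxidative ATP shares and
    carbon-flux shares, and screens single-node knock-outs/knock-ins for
    regulatory drivers of the metabolic switch. Ships a seeded generator for a
    coupled toy regulatory/metabolic system with a planted hypoxia-type driver
    and synthetic expression contrasts, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
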