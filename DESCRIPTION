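Package: twinspace
Title: Geographically Weighted Twin Models for Mapping Genetic and
    Environmental Influences
Version: 0.1.0
Authors@R:
    person("twinspace", "developers", email = "maintainers@twinspace.dev",
           role = c("aut", "cre"))
Description: Fits classical twin ACE/ADE variance decomposition models by
    weighted full-information maximum likelihood at many geographic target
    locations, so that additive-genetic (A), shared-environmental (C) and
    non-shared-environmental (E) influences on a quantitative trait can be
    mapped across a country. Every twin pair contributes to the estimate at
    every target location, down-weighted by an inverse power of its distance
    from the target. Includes quantitative sex-limitation models, Kish
    effective sample sizes, a synthetic spatial twin-cohort generator with
    known location-varying aetiology, winsorized diverging map colouring,
    and a command-line pipeline (simulate, fit, map, sensitivity).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
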