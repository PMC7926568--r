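Package: hwfplan
Title: Needs-Based Health Workforce Planning and Supply Projection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A deterministic simulation engine for population needs-based
    health workforce planning. Projects the supply of health professional
    cadres with a stock-and-flow model (attrition, education-pipeline inflow,
    labour participation), projects needs-based workforce requirements from
    population demographics, trending health-status indicators and service
    norms (standard workloads in the WISN sense, work division across cadres,
    support-activity adjustment), and integrates the two into absolute gaps,
    staff availability ratios and wage-bill cost projections. Includes
    scenario validation from YAML/CSV configuration, pre-registered
    sensitivity variants, seeded Latin-hypercube parameter sweeps, and a
    synthetic scenario generator for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    lhs
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
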