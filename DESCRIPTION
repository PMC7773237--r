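Package: pastoralsim
Title: Agent-Based Simulation of Nomadic Pastoralist Movement on Dynamic
    Favorability Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to build seasonally dynamic, normalized favorability
    surfaces for arid rangelands (soil-adjusted vegetation index, surface and
    artificial water, slope, conflict incidence with a one-season lag, ethnic
    border proximity, land-tenure masks), to simulate monthly movement of
    nomadic pastoralist household agents over those surfaces with land-sharing
    negotiation on private land and drop-out to internally displaced status
    after repeated failed deals, and to analyse the resulting point patterns
    (per-district counts and change tables, Jenks natural-breaks
    classification, quadratic-kernel density surfaces, standard deviational
    ellipses). A seeded synthetic landscape generator provides district and
    ethnic-territory tessellations, seasonal vegetation with drought years,
    clustered conflict events, settlements, and water layers so the full
    pipeline runs without external geodata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
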