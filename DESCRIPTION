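Package: agelearn
Title: Age-Structured Models of Cultural Transmission and Demography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Deterministic recursions coupling stage-structured demography
    (an adapted Leslie matrix over five life stages) with the transmission of
    a dichotomous cultural trait through vertical, oblique, and horizontal
    learning whose balance changes over the life course.  The trait may raise
    or lower fertility or survival, feeding back on population growth, and may
    construct its own learning niche by eroding vertical contact time as it
    spreads.  Includes a scenario library of learning life histories
    (all-vertical, hunter-gatherer, agriculturalist, all-horizontal),
    parameter-sweep and neutral-comparison experiments, demographic
    rescue/collapse runs, and a stochastic individual-based twin of the
    recursions used as a verification oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
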