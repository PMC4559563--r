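Package: chemocomp
Title: Consumer-Resource Competition Dynamics in Chemostat Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and stability analysis for the Tilman family of
    consumer-resource competition models with chemostat resource supply.
    Provides closed-form stationary points for systems of up to two
    consumers and two resources (Holling type II and Liebig-minimum
    growth), Jacobian eigenvalue classification including the determinant
    sign criterion for two-consumer coexistence, deterministic forward
    Euler integration with detection of transient visits to saddle points,
    bundled worked-example scenarios, and a random-system sampler for
    property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
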