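Package: iondamage
Title: Analytical DNA Damage Yields for Light Ions from Track-Structure
    Simulations
Version: 1.0.0
Authors@R:
    person("Iondamage", "Developers", email = "iondamage@example.org",
           role = c("aut", "cre"))
Description: Evaluates analytical, LET-dependent yields of DNA strand
    breakage (SB), single-strand breaks (SSB), double-strand breaks (DSB),
    DSB clusters and DSB sites for fully stripped ions from hydrogen to
    neon, as parametrized from PARTRAC track-structure simulations of an
    in-silico irradiated human cell nucleus (6.6 Gbp).  Ships the fitted
    parameter database (135 parameter sets: 9 ions x 5 damage classes x
    total/direct/indirect channels), a constrained relative-least-squares
    refitting protocol with synthetic-data generators for parameter
    recovery studies, relative biological effectiveness (RBE) and
    dose-weighted mixed-field calculators, the underlying strand-break
    induction probabilities, and a classifier that scores explicit break
    lists into SSB, DSB, DSB clusters and DSB sites.  A command-line
    entry point exposes the main operations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
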