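Package: riverval
Title: Hierarchical Multi-Attribute Value and Utility Assessment for River
    Rehabilitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An engine for multi-attribute value theory (MAVT/MAUT) assessment
    of the ecological state of rivers. Represents objectives hierarchies with
    measurable attributes at the leaves, single-attribute value functions
    elicited by the bisection method, swing and direct-rating weight
    elicitation with group-median consolidation, additive, minimum,
    multiplicative (synergy-factor) and mixed additive-minimum aggregation,
    and certainty-equivalent utility functions capturing expert risk attitude
    at the root objective. Ships a transcription of an elicited river
    rehabilitation objectives hierarchy and expert preference tables, seeded
    generators for synthetic hierarchies, preferences and river states, and an
    analysis layer that quantifies the effect of four common simplifications:
    few objectives, linear value functions, additive aggregation, and risk
    neutrality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
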