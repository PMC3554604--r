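Package: teotimer
Title: Temporal Representation, Reasoning and Timeline Comparison for
    Vaccine Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Machine-understandable representation of vaccine adverse-event
    reports: events, time instants and intervals, durations, granularity and
    Allen-style qualitative temporal relations.  Includes a path-consistency
    reasoner over the 13 Allen interval relations with calendar date inference
    along duration-offset chains, normalization of narrative time expressions
    (partial dates, duration words, periodic patterns) against structured-field
    anchors, ontology-based event-name normalization with a packaged lexicon
    excerpt (adverse-event, MedDRA and vaccine terms), deterministic Turtle
    serialization of temporal graphs including the annotated-axiom time-offset
    pattern, vaccination-anchored timeline construction, cross-report timeline
    comparison (shared-symptom offsets, symptom frequencies, order reversals),
    and a seeded generator of report fixtures with known ground-truth timelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
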