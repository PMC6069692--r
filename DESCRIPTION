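Package: dirtlink
Title: Direct Temporal Relation Identification in Clinical Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying direct temporal relations between time
    expressions and clinical event mentions in narrative text. Provides a
    before/after/overlap relation algebra with transitive closure and
    contradiction reporting, a deterministic constituency-based rule engine
    that decides whether a time-event pair is syntactically direct
    (modification or shared predicate, with prepositional-phrase,
    coordination and type-preserving-phrase exceptions), a cost-sensitive
    four-way SVM classifier over lexical, syntactic and predicate-argument
    features with rule-based post-processing, closure-extended evaluation
    metrics and Cohen's kappa, readers and writers for a standoff XML
    annotation dialect with sidecar linguistic analyses, and a seeded
    synthetic corpus generator covering every rule path.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
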