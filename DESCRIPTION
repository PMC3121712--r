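Package: chessr
Title: Canonical Semantic Identifiers and RDF Encodings for Chemical Entities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic, database-independent canonical identifiers and RDF
    encodings for molecules, atoms, bonds, functional-group fragments,
    descriptors, chemical configurations, and reactions, anchored on InChI
    canonicalization. Provides atom-centered depth-limited fragmentation for
    fingerprint-style similarity ranking, an in-process triple store with
    Turtle/N-Triples serialization, SPARQL query generation, substructure
    search, provenance-filtered descriptor retrieval, Rule-of-Five
    classification, bond-dissociation-enthalpy window queries, and reaction
    candidate matching, together with a deterministic fixture generator and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    digest,
    igraph,
    methods,
    stats,
    utils
SystemRequirements: OpenBabel (obabel on PATH)
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
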