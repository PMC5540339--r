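Package: ontoforms
Title: Ontology-Driven Web Form Generation and Semantic Data Acquisition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates Web assessment forms from an OWL form-specification
    ontology combined with an XML layout configuration, and transforms
    submitted answers into a semantically enriched, queryable RDF graph of
    observation individuals linked to domain-ontology descriptions. Ships a
    generic form/data ontology, a small clinical functional-assessment style
    domain ontology, an example back-pain form, a seeded synthetic-submission
    generator, and a SPARQL subset engine for focus-based and
    description-component retrieval of acquired observations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    digest,
    utils,
    stats,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
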