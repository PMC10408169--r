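Package: adonto
Title: Ontology-Based Integration of Alzheimer's Disease Clinical Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds a computational ontology (TBox) for Alzheimer's-disease
    clinical data centred on neuropsychological assessments, lifts ADNI-shaped
    CSV tables into an RDF ABox through a declarative field-to-path mapping
    rule language with deterministic individual minting, and answers SPARQL
    SELECT queries over the populated graph with rdfs:subClassOf inference via
    property paths. Includes Turtle and RDF/XML serialization, allValuesFrom
    restriction validation, a synthetic fixture generator emulating
    phase-dependent ADNI field dialects, and a command-line loader.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
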