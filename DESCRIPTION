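Package: sempheno
Title: Semantic Phenotype Annotation and Reasoning for Taxonomic Species Descriptions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for representing taxonomic species descriptions as formal
    ontology data. Character matrices, specimens and entity-quality (EQ)
    phenotype annotations are modelled in a restricted OWL fragment; a
    structural subsumption reasoner with property-chain materialization
    propagates phenotype classes from character states to museum specimens
    via a denotes-only pattern. Includes Manchester-subset parsing and
    rendering, Turtle and RDF/XML serialization, natural-language treatment
    parsing and rendering, NEXUS and CSV matrix export, ontology class-usage
    and anatomical/quality partition queries, dichotomous identification key
    evaluation, minimal diagnosis search, and a seeded synthetic-study
    generator for property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
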