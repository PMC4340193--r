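Package: owlgen
Title: Code-First OWL Ontology Generation from Annotated Object Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Introspects an annotated object-oriented data model (classes,
    typed fields, single inheritance, enumerations, instances) into a portable
    intermediate representation and transforms it into an OWL ontology:
    classes become owl:Class nodes, atomic fields datatype properties,
    reference and collection fields object properties, and semantic markers
    (equivalence, symmetry, inverses, value and cardinality constraints)
    become the corresponding OWL constructs, with property restrictions
    attached as anonymous superclasses.  The emitted triple graph serializes
    to RDF/XML, abbreviated RDF/XML, Turtle, N-Triples and N3, with parse-back
    and graph-isomorphism support.  Ships an EEG/ERP experiment-metadata
    domain model and a seeded synthetic instance generator as a worked
    fixture, plus a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    jsonlite,
    yaml,
    xml2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
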