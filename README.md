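# owlgen

Code-first OWL ontology generation from annotated object models, in R.

Research software that stores its records in conventional object-oriented
data layers (plain data classes over a relational store) often needs to
publish those records — and their schema — as a Semantic Web ontology, for
example to register a data portal with a neuroinformatics resource index.
`owlgen` does that translation: it takes a declared object model (classes
with typed fields, single inheritance, enumerations, and optional instance
records), together with lightweight *semantic markers* that say things the
object model itself cannot (class equivalences, symmetric or transitive
relations, value and cardinality constraints), and emits an OWL ontology
document in your choice of RDF syntax. It ships with an EEG/ERP
experiment-metadata model as a complete worked fixture.

## The mapping

Structure first. For a model with classes `C₁ … Cₙ`:

* every class `Cᵢ` becomes an `owl:Class`, annotated with its dotted source
  name through a `semantic:javaclass` annotation property;
* `Cᵢ extends Cⱼ` becomes `Cᵢ rdfs:subClassOf Cⱼ`;
* every atomic field becomes an `owl:DatatypeProperty` with
  `rdfs:domain` the declaring class and `rdfs:range` its XSD datatype
  (string → `xsd:string`, integer → `xsd:integer`, decimal → `xsd:double`,
  boolean → `xsd:boolean`, date → `xsd:date`, datetime → `xsd:dateTime`);
* every reference or collection field becomes an `owl:ObjectProperty`
  ranging over the target class;
* enumerations become classes equivalent to an `owl:oneOf` list with one
  named individual per literal;
* every instance record becomes a named, typed individual
  (`Person_0`, `Person_1`, …) with literal assertions for atomic values and
  object-property assertions for references.

Then enrichment. Each semantic marker maps onto exactly one OWL construct:

| marker               | OWL construct emitted                                   |
|----------------------|---------------------------------------------------------|
| `EquivalentClass`    | `owl:equivalentClass` on the class                       |
| `SameAs` / `DifferentFrom` | `owl:sameAs` / `owl:differentFrom` on the class    |
| `AllDifferent`       | `rdf:type` of the referenced AllDifferent resource       |
| `EquivalentProperty` | `owl:equivalentProperty` on the property                 |
| `Symmetric` / `Transitive` | `rdf:type owl:SymmetricProperty` / `owl:TransitiveProperty` |
| `Inverse`            | `owl:inverseOf` on the property                          |
| `AllValuesFrom` / `SomeValuesFrom` | an anonymous `owl:Restriction` superclass  |
| `Cardinality` / `MinCardinality` / `MaxCardinality` | an `owl:Restriction` with an `xsd:int` literal |

Value and cardinality constraints follow the classic restriction pattern: an
anonymous `owl:Restriction` node with `owl:onProperty`, wired as
`rdfs:subClassOf` of the declaring class. The string-valued form of
`SomeValuesFrom` produces an `owl:DataRange` whose `owl:oneOf` is an RDF
list of string literals.

Supported output syntaxes: `rdfxml`, `rdfxml-abbrev`, `turtle`, `ntriples`,
`n3` — all functionally equivalent (their parse-backs are mutually
isomorphic RDF graphs; `graphs_isomorphic()` is part of the package).

## Worked example

The annotated `Person` bean — equivalent to an external `TestedSubject`
class, a someValuesFrom constraint on `firstname`, cardinality 1 on
`dateofBirth`, minimum cardinality 1 on `researchGroups` — plus one Person
and one ResearchGroup record:

```r
library(owlgen)
model <- parse_model_document(
  system.file("extdata", "annotated-person.yaml", package = "owlgen"), "yaml")
g <- map_model(model, list(
  instance_record("Person", "p1",
                  list(id = 7, firstname = "Jan", researchGroups = "g1")),
  instance_record("ResearchGroup", "g1")))
cat(serialize_graph(g, "turtle"))
```

prints (abridged):

```turtle
_:b4 a owl:Restriction ;
    owl:cardinality "1"^^xsd:int ;
    owl:onProperty this:dateofBirth .
_:b5 a owl:Restriction ;
    owl:minCardinality "1"^^xsd:int ;
    owl:onProperty this:researchGroups .
this:Person a owl:Class ;
    semantic:javaclass "cz.zcu.kiv.Person" ;
    rdfs:subClassOf _:b1 , _:b4 , _:b5 ;
    owl:equivalentClass <http://cz.zcu.kiv/TestedSubject> .
this:Person_0 a this:Person ;
    this:firstname "Jan" ;
    this:id "7"^^xsd:integer ;
    this:researchGroups this:ResearchGroup_0 .
this:firstname a owl:DatatypeProperty ;
    rdfs:domain this:Person ;
    rdfs:range xsd:string .
```

Every class gained an `owl:Class` node carrying its source name, every field
a typed property, each marker its restriction or axiom, and the records
became the `Person_0` / `ResearchGroup_0` individuals.

The same pipeline is available from the shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "owlgen.R", package = "owlgen"))')" \
  generate --fixture eeg --fixture-n 2 --seed 1 --syntax turtle --out -
```

(`generate` also accepts `--model-doc model.yaml`, `--native defs.R
--classes A,B`, `--instances records.json`, `--base-iri`, `--naming`;
`validate` prints the model/instance violation report; `syntaxes` lists the
supported output names.)

## The bundled EEG/ERP fixture

`build_domain_model()` returns an electrophysiology experiment-metadata
model: one class per metadata group (experimental protocol, environment,
tested subject, hardware and software equipment, electrodes, data
digitalization, signal analysis, data presentation, signal artifacts) plus
the `Experiment` / `Scenario` / `Data` hubs. `generate_instances(n, seed)`
produces `n` experiments, each linked to a fresh Person, Scenario,
HardwareEquipment and Data record, with seeded synthetic attribute values —
enough to exercise every mapping feature, including an exact
triple-count-linearity check, without any external data.

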