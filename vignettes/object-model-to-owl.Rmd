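---
title: "Mapping annotated object models to OWL: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping annotated object models to OWL: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(owlgen)
```

## The problem

Object-oriented data layers describe a domain with classes, typed fields and
inheritance; OWL describes it with classes, global properties, individuals
and axioms. The expressivity gap runs in one direction: everything an
object model can say has an OWL counterpart, but OWL can additionally state
equivalences, symmetric/transitive/inverse relations, and value or
cardinality constraints that no field declaration carries. `owlgen` closes
the gap with a two-stage transformation: a *structural* mapping that is
total on the object model, and a *semantic* mapping driven by markers the
modeller attaches where the extra meaning lives.

Everything flows through a portable intermediate representation (IR):
`class_model()`, `field_model()`, `semantic_annotation()` and
`instance_record()` values. Two front ends produce it — introspection of
native S4 declarations (`scan_native_model()`), and the YAML/JSON model
documents (`parse_model_document()`) — and both are required by the test
suite to yield byte-identical IR for paired declarations. The mapping
engine only ever sees the IR, so its behaviour cannot depend on which front
end was used.

## Structural mapping

For every class the mapper emits an `owl:Class` under the configured base
IRI (`mapping_config(base_iri = …)`, default `http://example.org/model#`),
annotated with the class's dotted source name through the
`semantic:javaclass` annotation property (local name configurable).
Superclass links become `rdfs:subClassOf`; only the directly declared link
is emitted, so a chain A ← B ← C yields exactly two subclass triples.

Fields become properties. OWL properties are global — they are not owned by
a class the way fields are — so the mapper builds a model-wide property
table first. A field name declared by several classes with the *same* range
yields one property whose domain is an `owl:unionOf` class expression over
the declaring classes. Conflicting ranges are a hard error: silently
merging, or letting the last declaration win, would corrupt the ontology in
a way no downstream consumer could detect. Inherited fields are mapped once,
on the declaring superclass; subclasses reach them through `rdfs:subClassOf`.

Enumerations map to the standard idiom: one named individual per literal
(`Gender_MALE`, …) and an `owl:equivalentClass` link to an anonymous class
whose `owl:oneOf` lists those individuals in declaration order.

Instance records map to named individuals. Naming is configurable:
`sequential` (default) numbers individuals `Class_0, Class_1, …` per class
in record order; `identifier-field` uses the value of the class's
identifier field (`Class_42`). Minting is deterministic and checked for
injectivity — a collision aborts the run rather than aliasing two records.
Atomic values become typed literals matching the property range; reference
values become object-property assertions. Individuals are minted in a first
pass and asserted in a second, so reference cycles resolve without
duplication. An absent field value simply produces no assertion; there is
no null literal.

## Semantic mapping

Thirteen markers are supported; each maps onto exactly one OWL construct
(see the README table). Four are class-level (`EquivalentClass`, `SameAs`,
`DifferentFrom`, `AllDifferent`), nine field-level. The parameter slot is
determined by the marker: cardinality markers carry a non-negative integer,
`Symmetric`/`Transitive` carry nothing, `SomeValuesFrom` carries either a
resource IRI or a list of string values, and the rest carry a resource IRI.
Validation rejects a marker whose slot is misfiled, a marker on the wrong
level, and the object-property-only markers (`Symmetric`, `Transitive`,
`Inverse`) on atomic fields.

Value and cardinality constraints become anonymous `owl:Restriction`
classes wired as `rdfs:subClassOf` of the *declaring* class — the only
placement the source material for this mapping ever exhibits, and the one
Protégé-style tools render under the class's own description. The
string-valued `SomeValuesFrom` form emits an `owl:DataRange` whose
`owl:oneOf` is an RDF list of plain string literals. The parameter is
emitted verbatim as a string even when it looks like a URI; fidelity to the
established serialization was preferred over cleanup, and consumers that
want an IRI range can use the resource-parameterised form.

Two deliberate datatype asymmetries are kept because both conventions are
established in the target ecosystem: cardinality literals are typed
`xsd:int` (configurable via `cardinality_datatype`), while integer field
ranges use `xsd:integer`. Similarly, class-level `SameAs`/`DifferentFrom`/
`AllDifferent` are emitted on the class node as the marker table prescribes,
although OWL-DL purists would reserve them for individuals; this is recorded
behaviour, not an accident. `AllDifferent` emits a bare `rdf:type` of the
referenced resource with no `owl:distinctMembers` list — the mapping this
package implements defines nothing more for it.

`apply_semantics()` is idempotent. For IRI-object axioms this falls out of
triple-set semantics; for restrictions, which are blank nodes, the mapper
computes a signature (class, property, constraint predicate, constraint
object) for every restriction already in the graph and skips re-emission,
so re-running the enrichment adds no isomorphic duplicates.

## Graphs, serialization, equivalence

The `ontology_graph` container is a triple table (subject, predicate,
object with node types and literal datatype). Plain literals and
`xsd:string` literals are one value in RDF 1.1, so string literals are
normalised to plain on construction and on parse; this keeps cross-syntax
round trips isomorphic. Blank nodes appear only as restriction classes,
data ranges, union-domain class expressions and RDF list cells.

Serialization is deterministic: triples are put into a canonical order
(subjects, then `rdf:type` first among predicates, then objects) before
emission, so a fixed graph yields byte-identical documents across runs.
Five syntaxes are emitted and parsed: `rdfxml`, `rdfxml-abbrev` (typed node
elements with singly-referenced blank nodes nested inline), `turtle`,
`ntriples` and `n3` (the emitted N3 is the Turtle subset, which is valid
N3). OWL/XML and the N3 pretty-print sub-dialects are not emitted;
`supported_syntaxes()` is the capability query, and the functional
equivalence contract covers exactly what it reports. Because no RDF library
ships with the R ecosystem in use here, the N-Triples/Turtle serializers and
parsers are implemented in-package (the XML layer of RDF/XML rests on
`xml2`); the test suite cross-checks every emitted document against an
independent Python RDF parser to guard against dialect drift.

Equality of graphs is isomorphism: equality of triple sets up to a
bijective renaming of blank nodes. `graphs_isomorphic()` compares ground
triples directly, then partitions blank nodes by iterative signature
refinement (a blank's colour is the multiset of its incident triple shapes,
with neighbouring blanks abstracted to colours) and resolves any remaining
ambiguity by backtracking inside the refined classes. Refinement alone
separates every blank our mapper produces; the backtracking branch exists
for genuinely interchangeable blanks, which the property tests exercise
explicitly.

## The synthetic fixture and what the tests show

`build_domain_model()` ships an EEG/ERP experiment-metadata model: ten
metadata-group classes plus the Experiment/Scenario/Data hubs, a Gender
enumeration, and a Person class carrying all thirteen markers (one of each,
including the worked-example constraints on `firstname`, `dateofBirth` and
`researchGroups`). `generate_instances(n, seed)` yields `n` experiments,
each linked to one fresh Person, Scenario, HardwareEquipment and Data
record — five records per experiment, every record of a class populating
the same fields with pool-sampled values. Field lists of the satellite
classes are intentionally minimal (two to four atomic fields); only their
linkage structure is domain-constrained, and the attribute pools are
invented synthetic content.

That constant per-experiment shape makes the scaling claim exactly
testable: the mapped triple count must satisfy `count(n) = a + b·n` with
`a`, `b` fitted from `n = 1, 2` and verified at `n = 5, 10`, and a soft
wall-clock check at `n = 100` vs `n = 400` guards against quadratic
behaviour. The suite runs the full cross-syntax equivalence matrix on the
fixture at `n = 2` and the scaling checks up to `n = 400` (roughly ten
thousand triples) — sizes chosen to exercise every code path many times
over while keeping the default test run fast.

What passing tests do *not* show: the fixture's values are synthetic, so
nothing is claimed about real portal databases, about models with fields
the IR cannot express (multiple inheritance, parameterised types beyond
single-element collections, behaviour/methods — all out of scope by
design), or about reasoning over the emitted ontology. The package emits
axioms; it does not check their global consistency.

## Degenerate inputs and tie-breaks

* An empty model maps to the ontology header alone; an empty graph
  serializes to prefix declarations only.
* `MinCardinality(0)` is vacuous but legal; negative cardinalities are
  rejected at validation and again by `build_restriction()`.
* Collections of atomics are rejected at validation: every printed use of a
  collection in the source conventions is class-valued, and relaxing this
  is explicitly a non-goal.
* Validation is a report, not an exception stream: `validate_model()`
  returns every violation with class/field/instance coordinates, and a
  model with an empty report is accepted by every downstream operation.
* Field discovery order is declaration order everywhere, which — together
  with canonical triple ordering — makes the whole pipeline deterministic;
  the CLI is a thin wrapper over the same functions and is tested to be
  byte-identical to a direct library call.
* The identifier marker feeds individual IRI minting and nothing else.

## Known limitations

`owl:intersectionOf`/`complementOf` have no marker (no source-model
counterpart exists to hang them on). The RDF/XML parser covers the node
element/property element subset the emitter and mainstream serializers
produce (including `rdf:ID` against `xml:base`, `rdf:nodeID`,
`rdf:datatype` and `rdf:parseType="Resource"`), not exotic constructs such
as `rdf:li` containers or property attributes. Language-tagged literals are
parsed but the tag is not modelled. These are acceptable for the package's
job — emitting and round-tripping its own ontologies — and are the first
things to extend if it outgrows that job.
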