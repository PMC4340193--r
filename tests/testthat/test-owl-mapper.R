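test_that("the Person/ResearchGroup model maps to the printed structural axioms", {
  g <- map_structure(person_model())
  # classes with their source-class annotation
  expect_true(has_triple(g, paste0(BASE, "Person"), paste0(RDF, "type"),
                         paste0(OWL, "Class")))
  expect_true(has_triple(g, paste0(BASE, "ResearchGroup"), paste0(RDF, "type"),
                         paste0(OWL, "Class")))
  expect_true(has_triple(g, paste0(BASE, "Person"), paste0(SEM, "javaclass"),
                         "cz.zcu.kiv.Person", o_type = "literal"))
  # object property researchGroups: Person -> ResearchGroup
  rg <- paste0(BASE, "researchGroups")
  expect_true(has_triple(g, rg, paste0(RDF, "type"), paste0(OWL, "ObjectProperty")))
  expect_true(has_triple(g, rg, paste0(RDFS, "domain"), paste0(BASE, "Person")))
  expect_true(has_triple(g, rg, paste0(RDFS, "range"), paste0(BASE, "ResearchGroup")))
  # datatype properties with XSD ranges
  expect_true(has_triple(g, paste0(BASE, "firstname"), paste0(RDFS, "range"),
                         paste0(XSD, "string")))
  expect_true(has_triple(g, paste0(BASE, "id"), paste0(RDFS, "range"),
                         paste0(XSD, "integer")))
  expect_true(has_triple(g, paste0(BASE, "firstname"), paste0(RDF, "type"),
                         paste0(OWL, "DatatypeProperty")))
})

test_that("an empty class list maps to the ontology header alone", {
  g <- map_structure(list())
  expect_equal(graph_size(g), 1L)
  expect_true(has_triple(g, "http://example.org/model", paste0(RDF, "type"),
                         paste0(OWL, "Ontology")))
})

test_that("a three-class chain emits exactly its transitive reduction", {
  model <- list(class_model("A"), class_model("B", superclass = "A"),
                class_model("C", superclass = "B"))
  g <- map_structure(model)
  sub <- g$triples[g$triples$p == paste0(RDFS, "subClassOf"), , drop = FALSE]
  got <- sort(paste(sub$s, sub$o))

  # oracle: brute-force transitive reduction of the declared closure
  closure <- matrix(FALSE, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  closure["B", "A"] <- TRUE; closure["C", "B"] <- TRUE; closure["C", "A"] <- TRUE
  reduction <- closure
  for (i in rownames(closure)) for (j in colnames(closure)) {
    if (closure[i, j]) for (k in rownames(closure)) {
      if (closure[i, k] && closure[k, j]) reduction[i, j] <- FALSE
    }
  }
  want <- sort(apply(which(reduction, arr.ind = TRUE), 1, function(idx) {
    paste(paste0(BASE, rownames(reduction)[idx[1]]),
          paste0(BASE, colnames(reduction)[idx[2]]))
  }))
  expect_identical(got, unname(want))
})

test_that("IRI minting follows the printed conventions and is deterministic", {
  expect_equal(mint_iri("class", "Person"), paste0(BASE, "Person"))
  expect_equal(mint_iri("property", "firstname"), paste0(BASE, "firstname"))
  expect_equal(mint_iri("individual", c("Person", "0")), paste0(BASE, "Person_0"))
  expect_identical(mint_iri("class", "Person"), mint_iri("class", "Person"))
  expect_error(mint_iri("class", "has space"), "invalid identifier")
})

test_that("atomic kinds map onto their XSD datatypes totally", {
  want <- c(string = "string", integer = "integer", decimal = "double",
            boolean = "boolean", date = "date", datetime = "dateTime")
  for (k in atomic_kinds()) {
    expect_equal(atomic_to_datatype(k), paste0(XSD, want[[k]]))
  }
})

test_that("instances become typed individuals with literal assertions", {
  m <- person_model()
  g <- map_structure(m)
  g <- map_instances(g, list(instance_record("Person", "p", list(firstname = "Jan"))))
  ind <- paste0(BASE, "Person_0")  # first sequential individual
  expect_true(has_triple(g, ind, paste0(RDF, "type"), paste0(BASE, "Person")))
  expect_true(has_triple(g, ind, paste0(BASE, "firstname"), "Jan",
                         o_type = "literal"))
  expect_equal(sum(g$triples$s == ind), 2L)
})

test_that("reference cycles map to exactly two individuals and two assertions", {
  model <- list(
    class_model("Node", fields = list(
      field_model("next", "reference", target_class = "Node"))))
  g <- map_structure(model)
  g2 <- map_instances(g, list(
    instance_record("Node", "n1", list(`next` = "n2")),
    instance_record("Node", "n2", list(`next` = "n1"))
  ))
  new_keys <- setdiff(triple_keys_of(g2), triple_keys_of(g))
  # hand-enumerated expectation for the 2-cycle
  want <- sort(c(
    paste("iri", paste0(BASE, "Node_0"), paste0(RDF, "type"), "iri",
          paste0(BASE, "Node"), "", sep = " | "),
    paste("iri", paste0(BASE, "Node_1"), paste0(RDF, "type"), "iri",
          paste0(BASE, "Node"), "", sep = " | "),
    paste("iri", paste0(BASE, "Node_0"), paste0(BASE, "next"), "iri",
          paste0(BASE, "Node_1"), "", sep = " | "),
    paste("iri", paste0(BASE, "Node_1"), paste0(BASE, "next"), "iri",
          paste0(BASE, "Node_0"), "", sep = " | ")
  ))
  expect_identical(sort(new_keys), want)
})

test_that("identifier-field naming mints ClassName_<id-value> IRIs", {
  m <- person_model()
  cfg <- mapping_config(individual_naming = "identifier-field")
  g <- map_structure(m, cfg)
  g <- map_instances(g, list(
    instance_record("Person", "p", list(id = 42, firstname = "Jan"))), cfg, m)
  expect_true(has_triple(g, paste0(BASE, "Person_42"), paste0(RDF, "type"),
                         paste0(BASE, "Person")))
})

test_that("same-named fields share one global property with a union domain", {
  model <- list(
    class_model("A", fields = list(
      field_model("label", "atomic", atomic_kind = "string"))),
    class_model("B", fields = list(
      field_model("label", "atomic", atomic_kind = "string"))))
  g <- map_structure(model)
  prop <- paste0(BASE, "label")
  expect_equal(sum(g$triples$s == prop & g$triples$p == paste0(RDF, "type")), 1L)
  dom <- g$triples[g$triples$s == prop & g$triples$p == paste0(RDFS, "domain"), ]
  expect_equal(nrow(dom), 1L)
  expect_equal(dom$o_type, "blank")
  union_head <- g$triples$o[g$triples$s == dom$o & g$triples$p == paste0(OWL, "unionOf")]
  expect_setequal(rdf_list_values(g, union_head), paste0(BASE, c("A", "B")))

  conflicting <- list(
    class_model("A", fields = list(
      field_model("label", "atomic", atomic_kind = "string"))),
    class_model("B", fields = list(
      field_model("label", "atomic", atomic_kind = "integer"))))
  expect_error(map_structure(conflicting), "conflicting ranges")
})

test_that("enumerations map to a class equivalent to a oneOf list of individuals", {
  model <- list(class_model("Laterality", is_enumeration = TRUE,
                            enum_literals = c("LEFT", "RIGHT")))
  g <- map_structure(model)
  cls <- paste0(BASE, "Laterality")
  eq <- g$triples[g$triples$s == cls & g$triples$p == paste0(OWL, "equivalentClass"), ]
  expect_equal(nrow(eq), 1L)
  expect_equal(eq$o_type, "blank")
  head <- g$triples$o[g$triples$s == eq$o & g$triples$p == paste0(OWL, "oneOf")]
  expect_identical(rdf_list_values(g, head),
                   paste0(BASE, c("Laterality_LEFT", "Laterality_RIGHT")))
  for (lit in c("LEFT", "RIGHT")) {
    expect_true(has_triple(g, paste0(BASE, "Laterality_", lit),
                           paste0(RDF, "type"), cls))
  }
})

test_that("classes and properties are in bijection with the source model", {
  set.seed(33)
  for (trial in 1:4) {
    n <- sample(2:5, 1)
    nms <- paste0("K", seq_len(n))
    model <- lapply(seq_len(n), function(i) {
      class_model(nms[[i]], fields = list(
        field_model(paste0("k", i, "x"), "atomic", atomic_kind = "string"),
        field_model(paste0("k", i, "r"), "reference",
                    target_class = nms[[sample(n, 1)]])))
    })
    g <- map_structure(model)
    df <- g$triples
    base_classes <- df$s[df$p == paste0(RDF, "type") & df$o == paste0(OWL, "Class") &
                           df$s_type == "iri" & startsWith(df$s, BASE)]
    expect_length(base_classes, n)
    props <- df$s[df$p == paste0(RDF, "type") &
                    df$o %in% paste0(OWL, c("DatatypeProperty", "ObjectProperty"))]
    expect_length(unique(props), 2L * n)
  }
})

test_that("mapped triple counts are exactly affine in the instance count", {
  model <- build_domain_model()
  ns <- c(1L, 2L, 5L, 10L)
  counts <- vapply(ns, function(n) {
    graph_size(map_model(model, generate_instances(n, seed = 1)))
  }, numeric(1))
  b <- counts[[2L]] - counts[[1L]]
  a <- counts[[1L]] - b
  expect_identical(counts, a + b * ns)
})

test_that("semantic markers on object-only constructs reject atomic fields", {
  model <- list(class_model("A", fields = list(
    field_model("x", "atomic", atomic_kind = "string",
                annotations = list(semantic_annotation("Transitive"))))))
  expect_error(map_structure(model), "does not validate")
})

test_that("the annotated Person model reproduces the printed enriched axioms", {
  m <- annotated_person_model()
  g <- apply_semantics(map_structure(m), m)
  person <- paste0(BASE, "Person")
  expect_true(has_triple(g, person, paste0(OWL, "equivalentClass"),
                         "http://cz.zcu.kiv/TestedSubject"))
  r <- restrictions_of(g, person)
  expect_equal(nrow(r), 3L)
  # owl:cardinality "1"^^xsd:int on dateofBirth
  card <- r[r$on_property == paste0(BASE, "dateofBirth"), ]
  expect_equal(card$predicate, paste0(OWL, "cardinality"))
  expect_equal(card$object, "1")
  expect_equal(card$object_dt, paste0(XSD, "int"))
  # owl:minCardinality "1"^^xsd:int on researchGroups
  minc <- r[r$on_property == paste0(BASE, "researchGroups"), ]
  expect_equal(minc$predicate, paste0(OWL, "minCardinality"))
  expect_equal(minc$object, "1")
  # owl:someValuesFrom DataRange oneOf (GivenNames) on firstname
  svf <- r[r$on_property == paste0(BASE, "firstname"), ]
  expect_equal(svf$predicate, paste0(OWL, "someValuesFrom"))
  expect_equal(svf$object_type, "blank")
  expect_true(has_triple(g, svf$object, paste0(RDF, "type"),
                         paste0(OWL, "DataRange")))
  head <- g$triples$o[g$triples$s == svf$object & g$triples$p == paste0(OWL, "oneOf")]
  expect_identical(rdf_list_values(g, head), "http://cz.zcu.kiv/GivenNames")
})

test_that("apply_semantics is idempotent and the identity on unannotated models", {
  m0 <- person_model()
  g0 <- map_structure(m0)
  expect_identical(apply_semantics(g0, m0)$triples, g0$triples)

  m <- annotated_person_model()
  g1 <- apply_semantics(map_structure(m), m)
  g2 <- apply_semantics(g1, m)
  expect_equal(graph_size(g2), graph_size(g1))
  expect_true(graphs_isomorphic(g1, g2))
})
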