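test_that("an empty model and the worked Person model validate cleanly", {
  expect_equal(nrow(validate_model(list())), 0L)
  expect_equal(nrow(validate_model(person_model())), 0L)
  expect_equal(nrow(validate_model(annotated_person_model())), 0L)
})

test_that("field shape violations are reported with coordinates, not thrown", {
  bad <- list(class_model("A", fields = list(
    field_model("x", "atomic", atomic_kind = "string", target_class = "B")
  )), class_model("B"))
  rep <- validate_model(bad)
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$class, "A")
  expect_equal(rep$field, "x")

  # collections of atomics have no resolvable target class
  rep2 <- validate_model(list(class_model("A", fields = list(
    field_model("xs", "collection", target_class = "string")
  ))))
  expect_gt(nrow(rep2), 0L)
  expect_match(rep2$message[1], "not defined")
})

test_that("naming and inheritance invariants are enforced", {
  rep <- validate_model(list(class_model("A"), class_model("A")))
  expect_match(rep$message, "duplicate class", all = FALSE)

  rep <- validate_model(list(class_model("A", fields = list(
    field_model("x", "atomic", atomic_kind = "string"),
    field_model("x", "atomic", atomic_kind = "string")
  ))))
  expect_match(rep$message, "duplicate field", all = FALSE)

  rep <- validate_model(list(class_model("A", superclass = "Missing")))
  expect_match(rep$message, "superclass 'Missing'", all = FALSE)

  rep <- validate_model(list(class_model("A", superclass = "B"),
                             class_model("B", superclass = "A")))
  expect_match(rep$message, "cycle", all = FALSE)

  rep <- validate_model(list(class_model("A", fields = list(
    field_model("x", "atomic", atomic_kind = "string", is_identifier = TRUE),
    field_model("y", "atomic", atomic_kind = "string", is_identifier = TRUE)
  ))))
  expect_match(rep$message, "identifier", all = FALSE)
})

test_that("annotation markers are checked for level, slot and sign", {
  probe <- function(ann, level = "field") {
    if (level == "field") {
      list(class_model("A"), class_model("B", fields = list(
        field_model("r", "reference", target_class = "A", annotations = list(ann)))))
    } else {
      list(class_model("A", annotations = list(ann)))
    }
  }
  expect_match(validate_model(probe(semantic_annotation("NoSuchMarker",
    resource = "http://x/")))$message, "unknown annotation marker", all = FALSE)
  # cardinality marker with a resource instead of a number
  expect_match(validate_model(probe(semantic_annotation("Cardinality",
    resource = "http://x/")))$message, "wrong parameter slot", all = FALSE)
  expect_match(validate_model(probe(semantic_annotation("Cardinality",
    number = -1)))$message, "negative", all = FALSE)
  # class-level marker on a field and vice versa
  expect_match(validate_model(probe(semantic_annotation("EquivalentClass",
    resource = "http://x/")))$message, "not allowed at field level", all = FALSE)
  expect_match(validate_model(probe(semantic_annotation("Cardinality", number = 1),
    level = "class"))$message, "not allowed at class level", all = FALSE)
  # object-property-only marker on an atomic field
  rep <- validate_model(list(class_model("A", fields = list(
    field_model("x", "atomic", atomic_kind = "string",
                annotations = list(semantic_annotation("Symmetric")))))))
  expect_match(rep$message, "object property", all = FALSE)
})

test_that("instances are validated for class, shape and reference integrity", {
  m <- person_model()
  good <- list(
    instance_record("Person", "p1", list(firstname = "Jan", researchGroups = "g1")),
    instance_record("ResearchGroup", "g1")
  )
  expect_equal(nrow(validate_model(m, good)), 0L)

  expect_match(validate_model(m, list(instance_record("Nope", "x")))$message,
               "unknown class", all = FALSE)
  expect_match(validate_model(m, list(
    instance_record("Person", "p1", list(firstname = 3))
  ))$message, "does not match kind", all = FALSE)
  expect_match(validate_model(m, list(
    instance_record("Person", "p1", list(researchGroups = "ghost"))
  ))$message, "unknown instance id", all = FALSE)
  # referenced instance of the wrong class
  expect_match(validate_model(m, list(
    instance_record("Person", "p1", list(researchGroups = "p2")),
    instance_record("Person", "p2")
  ))$message, "expected 'ResearchGroup'", all = FALSE)
})

test_that("validation is idempotent and order-insensitive", {
  m <- c(annotated_person_model(), list(
    class_model("Equipment", fields = list(
      field_model("producer", "atomic", atomic_kind = "string"))),
    class_model("Amplifier", superclass = "Equipment")
  ))
  r1 <- validate_model(m)
  expect_identical(r1, validate_model(m))
  set.seed(11)
  for (i in 1:5) {
    perm <- sample(seq_along(m))
    expect_equal(nrow(validate_model(m[perm])), nrow(r1))
  }
})

test_that("a validated model is accepted by the whole downstream pipeline", {
  set.seed(4)
  for (trial in 1:5) {
    n_cls <- sample(2:4, 1)
    nms <- paste0("C", seq_len(n_cls))
    model <- lapply(seq_len(n_cls), function(i) {
      fields <- list(
        field_model(paste0("f", i, "a"), "atomic",
                    atomic_kind = sample(atomic_kinds(), 1)))
      if (i > 1) {
        fields <- c(fields, list(
          field_model(paste0("f", i, "r"), "reference", target_class = nms[i - 1])))
      }
      class_model(nms[i], paste0("pkg.", nms[i]), fields = fields)
    })
    expect_equal(nrow(validate_model(model)), 0L)
    g <- map_model(model)
    expect_s3_class(g, "ontology_graph")
    expect_true(graph_size(g) > 0)
    for (s in supported_syntaxes()) {
      expect_silent(parse_document(serialize_graph(g, s), s))
    }
  }
})
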