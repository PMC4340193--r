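# Both front ends -- native S4 declarations and portable model documents --
# must land on the identical IR.

native_person_env <- function() {
  env <- new.env(parent = globalenv())
  methods::setClass("ResearchGroup", representation(), where = env)
  methods::setClass("Person", representation(
    id = "integer", firstname = "character",
    researchGroups = list_of("ResearchGroup", where = env)), where = env)
  annotate_model("Person", package = "cz.zcu.kiv", identifier = "id")
  annotate_model("ResearchGroup", package = "cz.zcu.kiv")
  env
}

test_that("scanning the native Person declaration yields the worked IR", {
  on.exit(reset_model_registry())
  env <- native_person_env()
  m <- scan_native_model(c("Person", "ResearchGroup"), where = env)
  expect_length(m, 2L)
  p <- m[[1L]]
  expect_equal(p$qualified_name, "cz.zcu.kiv.Person")
  expect_equal(vapply(p$fields, `[[`, character(1), "name"),
               c("id", "firstname", "researchGroups"))
  expect_equal(p$fields[[1L]]$kind, "atomic")
  expect_equal(p$fields[[1L]]$atomic_kind, "integer")
  expect_true(p$fields[[1L]]$is_identifier)
  expect_equal(p$fields[[2L]]$atomic_kind, "string")
  expect_equal(p$fields[[3L]]$kind, "collection")
  expect_equal(p$fields[[3L]]$target_class, "ResearchGroup")
})

test_that("a field-free, marker-free class scans to empty lists", {
  on.exit(reset_model_registry())
  env <- new.env(parent = globalenv())
  methods::setClass("Empty", representation(), where = env)
  m <- scan_native_model("Empty", where = env)
  expect_length(m[[1L]]$fields, 0L)
  expect_length(m[[1L]]$annotations, 0L)
})

test_that("native markers are carried into the IR as annotations", {
  on.exit(reset_model_registry())
  env <- native_person_env()
  methods::setClass("AnnPerson", representation(
    id = "integer", firstname = "character", dateofBirth = "Date",
    researchGroups = "ResearchGroupList"), where = env)
  annotate_model("AnnPerson", package = "cz.zcu.kiv", identifier = "id",
    annotations = list(semantic_annotation("EquivalentClass",
                                           resource = "http://cz.zcu.kiv/TestedSubject")),
    fields = list(
      firstname = list(semantic_annotation("SomeValuesFrom",
                                           string_values = "http://cz.zcu.kiv/GivenNames")),
      dateofBirth = list(semantic_annotation("Cardinality", number = 1)),
      researchGroups = list(semantic_annotation("MinCardinality", number = 1))))
  m <- scan_native_model(c("AnnPerson", "ResearchGroup"), where = env)
  p <- m[[1L]]
  expect_equal(p$annotations[[1L]]$marker, "EquivalentClass")
  expect_equal(p$annotations[[1L]]$resource, "http://cz.zcu.kiv/TestedSubject")
  fanns <- lapply(p$fields, `[[`, "annotations")
  names(fanns) <- vapply(p$fields, `[[`, character(1), "name")
  expect_equal(fanns$firstname[[1L]]$string_values, "http://cz.zcu.kiv/GivenNames")
  expect_equal(fanns$dateofBirth[[1L]]$number, 1L)
  expect_equal(fanns$researchGroups[[1L]]$number, 1L)
})

test_that("unscannable classes fail with class and field named", {
  on.exit(reset_model_registry())
  env <- new.env(parent = globalenv())
  suppressWarnings(
    methods::setClass("Orphan", representation(buddy = "Buddy"), where = env))
  expect_error(scan_native_model("Orphan", where = env), "Orphan.*buddy",
               class = "simpleError")
  methods::setClass("Marked", representation(x = "character"), where = env)
  annotate_model("Marked", fields = list(
    nope = list(semantic_annotation("Cardinality", number = 1))))
  expect_error(scan_native_model("Marked", where = env), "unknown field 'nope'")
})

test_that("the model document front end matches native scanning exactly", {
  on.exit(reset_model_registry())
  env <- native_person_env()
  native <- scan_native_model(c("Person", "ResearchGroup"), where = env)
  doc <- parse_model_document(
    system.file("extdata", "listing-person.yaml", package = "owlgen"), "yaml")
  expect_identical(native, doc)
})

test_that("model documents parse from both YAML and JSON to one IR", {
  y <- parse_model_document(
    system.file("extdata", "annotated-person.yaml", package = "owlgen"), "yaml")
  j <- parse_model_document(jsonlite::toJSON(yaml::yaml.load(paste(readLines(
    system.file("extdata", "annotated-person.yaml", package = "owlgen")),
    collapse = "\n")), auto_unbox = TRUE), "json")
  expect_identical(y, j)
  expect_identical(y, annotated_person_model())
})

test_that("schema violations name the offending element", {
  expect_identical(parse_model_document("classes: []", "yaml"), list())
  err <- tryCatch(parse_model_document(
    "classes: [{name: A, fields: [{name: x, type: string, annotations: [{marker: Wat}]}]}]",
    "yaml"), error = identity)
  expect_s3_class(err, "owlgen_schema_error")
  expect_match(conditionMessage(err), "unknown marker 'Wat'")
  expect_match(conditionMessage(err), "classes\\[1\\].fields\\[1\\].annotations\\[1\\]")
  expect_error(parse_model_document("classes: [{name: A, wat: 1}]", "yaml"),
               "unknown key 'wat'")
  expect_error(parse_model_document("{}", "json"), "missing key 'classes'")
})

test_that("write_model_document round-trips the IR byte-for-byte", {
  for (m in list(person_model(), annotated_person_model(), build_domain_model())) {
    for (fmt in c("yaml", "json")) {
      expect_identical(parse_model_document(write_model_document(m, fmt), fmt), m)
    }
  }
})

test_that("rendering the IR natively and re-scanning is the identity", {
  on.exit(reset_model_registry())
  set.seed(21)
  kinds <- atomic_kinds()
  for (trial in 1:5) {
    n <- sample(2:4, 1)
    nms <- paste0("Gen", trial, "C", seq_len(n))
    model <- lapply(seq_len(n), function(i) {
      fields <- lapply(seq_len(sample(1:3, 1)), function(j) {
        field_model(paste0("g", trial, "f", i, j), "atomic",
                    atomic_kind = sample(kinds, 1),
                    is_identifier = FALSE)
      })
      if (i > 1 && runif(1) < 0.5) {
        fields <- c(fields, list(field_model(
          paste0("g", trial, "ref", i), sample(c("reference", "collection"), 1),
          target_class = nms[[1L]])))
      }
      class_model(nms[[i]], paste0("gen.", nms[[i]]),
                  superclass = if (i > 2 && runif(1) < 0.4) nms[[i - 1L]],
                  fields = fields)
    })
    expect_equal(nrow(validate_model(model)), 0L)
    env <- new.env(parent = globalenv())
    owlgen:::render_native_model(model, where = env)
    rescanned <- scan_native_model(vapply(model, `[[`, character(1), "simple_name"),
                                   where = env)
    expect_identical(rescanned, model)
  }
})

test_that("instance documents load, cross-link and reject bad records", {
  m <- person_model()
  recs <- load_instances(
    '[{"class": "Person", "id": "p1", "values": {"firstname": "Jan", "researchGroups": ["g1"]}},
      {"class": "ResearchGroup", "id": "g1"}]', m)
  expect_length(recs, 2L)
  expect_equal(recs[[1L]]$values$researchGroups, "g1")

  expect_error(load_instances('[{"class": "Nope", "id": "x"}]', m),
               "unknown class")
  expect_error(load_instances(
    '[{"class": "Person", "id": "p", "values": {"researchGroups": ["ghost"]}}]', m),
    "ghost")

  fix <- build_domain_model()
  recs <- generate_instances(3, seed = 5)
  txt <- write_instance_document(recs)
  loaded <- load_instances(txt, fix)
  expect_length(loaded, 15L)
  expect_identical(loaded, recs)
  exps <- Filter(function(r) r$class_name == "Experiment", loaded)
  expect_length(exps, 3L)
  for (e in exps) {
    expect_setequal(intersect(names(e$values),
                              c("testedSubject", "scenario", "hardware", "experimentData")),
                    c("testedSubject", "scenario", "hardware", "experimentData"))
  }
})
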