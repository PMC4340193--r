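# Shared fixtures: the worked Person/ResearchGroup bean models and small
# helpers for triple-set comparisons.

`%||%` <- function(a, b) if (is.null(a)) b else a

BASE <- "http://example.org/model#"
XSD <- "http://www.w3.org/2001/XMLSchema#"
OWL <- "http://www.w3.org/2002/07/owl#"
RDF <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS <- "http://www.w3.org/2000/01/rdf-schema#"
SEM <- "http://ns.owlgen.org/semantic#"

person_model <- function() {
  list(
    class_model("Person", "cz.zcu.kiv.Person", fields = list(
      field_model("id", "atomic", atomic_kind = "integer", is_identifier = TRUE),
      field_model("firstname", "atomic", atomic_kind = "string"),
      field_model("researchGroups", "collection", target_class = "ResearchGroup")
    )),
    class_model("ResearchGroup", "cz.zcu.kiv.ResearchGroup")
  )
}

annotated_person_model <- function() {
  list(
    class_model("Person", "cz.zcu.kiv.Person",
      annotations = list(
        semantic_annotation("EquivalentClass",
                            resource = "http://cz.zcu.kiv/TestedSubject")),
      fields = list(
        field_model("id", "atomic", atomic_kind = "integer", is_identifier = TRUE),
        field_model("firstname", "atomic", atomic_kind = "string",
                    annotations = list(semantic_annotation("SomeValuesFrom",
                      string_values = "http://cz.zcu.kiv/GivenNames"))),
        field_model("dateofBirth", "atomic", atomic_kind = "date",
                    annotations = list(semantic_annotation("Cardinality", number = 1))),
        field_model("researchGroups", "collection", target_class = "ResearchGroup",
                    annotations = list(semantic_annotation("MinCardinality", number = 1)))
      )),
    class_model("ResearchGroup", "cz.zcu.kiv.ResearchGroup")
  )
}

# flat string keys of a graph's triples (blank labels kept literal)
triple_keys_of <- function(graph) {
  df <- graph$triples
  sort(paste(df$s_type, df$s, df$p, df$o_type, df$o,
             ifelse(is.na(df$o_dt), "", df$o_dt), sep = " | "))
}

has_triple <- function(graph, s, p, o, o_type = "iri", o_dt = NA_character_) {
  df <- graph$triples
  any(df$s == s & df$p == p & df$o == o & df$o_type == o_type &
        (is.na(o_dt) & is.na(df$o_dt) | !is.na(df$o_dt) & !is.na(o_dt) & df$o_dt == o_dt))
}

# restrictions attached to a class: one row per (onProperty, predicate, object)
restrictions_of <- function(graph, cls_iri) {
  df <- graph$triples
  blanks <- df$o[df$s == cls_iri & df$p == paste0(RDFS, "subClassOf") &
                   df$o_type == "blank"]
  out <- lapply(blanks, function(bl) {
    rows <- df[df$s == bl, , drop = FALSE]
    if (!any(rows$p == paste0(RDF, "type") & rows$o == paste0(OWL, "Restriction"))) {
      return(NULL)
    }
    prop <- rows$o[rows$p == paste0(OWL, "onProperty")]
    crow <- rows[rows$p != paste0(RDF, "type") & rows$p != paste0(OWL, "onProperty"), ,
                 drop = FALSE]
    data.frame(on_property = prop, predicate = crow$p, object = crow$o,
               object_type = crow$o_type, object_dt = crow$o_dt,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# values of an RDF list starting at `head` (blank label)
rdf_list_values <- function(graph, head) {
  df <- graph$triples
  vals <- character()
  while (length(head) && head != paste0(RDF, "nil")) {
    vals <- c(vals, df$o[df$s == head & df$p == paste0(RDF, "first")])
    head <- df$o[df$s == head & df$p == paste0(RDF, "rest")]
  }
  vals
}
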