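#' Mapping configuration
#'
#' Bundles the knobs of the object-model-to-OWL transformation.
#'
#' @param base_iri Absolute base IRI ending in a fragment (`#`) or path (`/`)
#'   separator; all minted class, property and individual IRIs live under it.
#' @param source_annotation_local_name Local name of the annotation property
#'   that records each class's qualified source name (default `"javaclass"`).
#' @param semantic_ns Namespace IRI of that annotation property.
#' @param cardinality_datatype Datatype IRI stamped on cardinality-restriction
#'   literals.  Defaults to `xsd:int`, while atomic integer fields range over
#'   `xsd:integer`; both are deliberate and independently configurable.
#' @param individual_naming `"sequential"` (ClassName_0, ClassName_1, ... in
#'   record order) or `"identifier-field"` (ClassName_<value of the class's
#'   identifier field>).
#' @return An object of class `owlgen_config`.
#' @export
mapping_config <- function(base_iri = "http://example.org/model#",
                           source_annotation_local_name = "javaclass",
                           semantic_ns = "http://ns.owlgen.org/semantic#",
                           cardinality_datatype = XSD_INT,
                           individual_naming = c("sequential", "identifier-field")) {
  individual_naming <- match.arg(individual_naming)
  if (!grepl("^[A-Za-z][A-Za-z0-9+.-]*:", base_iri)) {
    stop("`base_iri` must be an absolute IRI, got: ", base_iri)
  }
  if (!grepl("[#/]$", base_iri)) {
    stop("`base_iri` must end with a '#' or '/' separator")
  }
  structure(
    list(base_iri = base_iri,
         source_annotation_local_name = source_annotation_local_name,
         semantic_ns = semantic_ns,
         cardinality_datatype = cardinality_datatype,
         individual_naming = individual_naming),
    class = "owlgen_config"
  )
}

ontology_iri <- function(cfg) sub("[#/]$", "", cfg$base_iri)

source_annotation_iri <- function(cfg) {
  paste0(cfg$semantic_ns, cfg$source_annotation_local_name)
}

#' Mint a resource IRI
#'
#' Deterministic IRI construction from model names and the configured base
#' namespace: classes become `base#SimpleName`, properties `base#fieldName`,
#' individuals `base#ClassName_<suffix>`.
#'
#' @param kind `"class"`, `"property"` or `"individual"`.
#' @param names For classes/properties, the single name; for individuals,
#'   `c(class_name, suffix)` where the suffix is the sequential index or the
#'   identifier-field value.
#' @param cfg A [mapping_config()].
#' @return The minted IRI string.
#' @examples
#' mint_iri("class", "Person")                 # ...#Person
#' mint_iri("individual", c("Person", "0"))    # ...#Person_0
#' @export
mint_iri <- function(kind, names, cfg = mapping_config()) {
  kind <- match.arg(kind, c("class", "property", "individual"))
  names <- as.character(names)
  if (any(!nzchar(names)) || any(grepl("[[:space:]#/]", names))) {
    stop("invalid identifier for IRI minting: ",
         paste(names, collapse = ", "))
  }
  if (kind == "individual") {
    if (length(names) != 2L) stop("individual minting needs c(class_name, suffix)")
    paste0(cfg$base_iri, names[[1L]], "_", names[[2L]])
  } else {
    if (length(names) != 1L) stop(kind, " minting needs a single name")
    paste0(cfg$base_iri, names[[1L]])
  }
}

#' Map an atomic kind to its XSD datatype
#'
#' Total function over [atomic_kinds()]: string, integer, decimal, boolean,
#' date and datetime map to `xsd:string`, `xsd:integer`, `xsd:double`,
#' `xsd:boolean`, `xsd:date` and `xsd:dateTime`.
#'
#' @param kind One of [atomic_kinds()].
#' @return The datatype IRI.
#' @export
atomic_to_datatype <- function(kind) {
  switch(match.arg(kind, atomic_kinds()),
    string   = XSD_STRING,
    integer  = XSD_INTEGER,
    decimal  = XSD_DOUBLE,
    boolean  = XSD_BOOLEAN,
    date     = XSD_DATE,
    datetime = XSD_DATETIME
  )
}
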