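#' Generate an ontology document in one call
#'
#' The full pipeline: validate, map structure, apply semantic annotations,
#' map instances, serialize.
#'
#' @param classes List of [class_model()] objects.
#' @param instances Optional list of [instance_record()] objects.
#' @param cfg A [mapping_config()].
#' @param syntax One of [supported_syntaxes()].
#' @return The ontology document as a single string.
#' @examples
#' model <- build_domain_model()
#' doc <- generate_ontology(model, syntax = "turtle")
#' @export
generate_ontology <- function(classes, instances = list(),
                              cfg = mapping_config(), syntax = "rdfxml") {
  serialize_graph(map_model(classes, instances, cfg), syntax)
}
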