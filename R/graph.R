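# In-memory RDF triple container.
#
# Triples are rows of a data frame.  Node encoding:
#   s        subject IRI or blank label;  s_type in {"iri","blank"}
#   p        predicate IRI
#   o        object IRI, blank label, or literal lexical form
#   o_type   one of "iri", "blank", "literal"
#   o_dt     literal datatype IRI, or NA for plain literals (plain == xsd:string)
# Blank labels are bare strings ("b1"); the type columns disambiguate.

triple_cols <- c("s", "s_type", "p", "o", "o_type", "o_dt")

empty_triples <- function() {
  data.frame(s = character(), s_type = character(), p = character(),
             o = character(), o_type = character(), o_dt = character(),
             stringsAsFactors = FALSE)
}

#' Create an ontology graph
#'
#' A set of RDF triples plus a namespace (prefix to IRI) table.  Most users
#' obtain graphs from [map_structure()] and friends rather than building them
#' triple by triple.
#'
#' @param triples A triple data frame (usually omitted).
#' @param namespaces Named character vector, prefix -> namespace IRI.
#' @return An object of class `ontology_graph`.
#' @export
ontology_graph <- function(triples = empty_triples(),
                           namespaces = default_namespaces()) {
  stopifnot(is.data.frame(triples), all(triple_cols %in% names(triples)))
  g <- list(triples = triples[triple_cols], namespaces = namespaces,
            blank_counter = next_blank_id(triples))
  class(g) <- "ontology_graph"
  g
}

default_namespaces <- function() {
  c(rdf = NS_RDF, rdfs = NS_RDFS, owl = NS_OWL, xsd = NS_XSD)
}

next_blank_id <- function(triples) {
  labs <- c(triples$s[triples$s_type == "blank"],
            triples$o[triples$o_type == "blank"])
  nums <- suppressWarnings(as.integer(sub("^b", "", labs)))
  if (length(nums) == 0L || all(is.na(nums))) 1L else max(nums, na.rm = TRUE) + 1L
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("<ontology_graph> %d triples, %d namespaces\n",
              nrow(x$triples), length(x$namespaces)))
  invisible(x)
}

#' Number of triples in a graph
#' @param graph An `ontology_graph`.
#' @return Integer triple count.
#' @export
graph_size <- function(graph) nrow(graph$triples)

# ---- node constructors (tagged lists) --------------------------------------

node_iri     <- function(iri) list(v = iri, t = "iri", dt = NA_character_)
node_blank   <- function(label) list(v = label, t = "blank", dt = NA_character_)
node_literal <- function(lex, datatype = NA_character_) {
  # plain literals and xsd:string are one and the same value space
  if (!is.na(datatype) && datatype == XSD_STRING) datatype <- NA_character_
  list(v = as.character(lex), t = "literal", dt = datatype)
}

# ---- mutable builder -------------------------------------------------------
# Mapping operations accumulate triples in an environment and freeze the
# result once; repeated rbind on data frames would be quadratic.

graph_builder <- function(graph) {
  b <- new.env(parent = emptyenv())
  b$base <- graph$triples
  b$cap <- 256L
  b$s <- character(256L); b$s_type <- character(256L); b$p <- character(256L)
  b$o <- character(256L); b$o_type <- character(256L); b$o_dt <- rep(NA_character_, 256L)
  b$n <- 0L
  b$namespaces <- graph$namespaces
  b$blank_counter <- graph$blank_counter
  # existing triples as a set, for duplicate suppression
  b$keys <- new.env(parent = emptyenv(), size = max(64L, nrow(graph$triples) * 2L))
  if (nrow(graph$triples)) {
    for (k in triple_keys(graph$triples)) assign(k, TRUE, envir = b$keys)
  }
  b
}

triple_keys <- function(df) {
  paste(df$s, df$s_type, df$p, df$o, df$o_type,
        ifelse(is.na(df$o_dt), "", df$o_dt), sep = "\r")
}

builder_fresh_blank <- function(b) {
  lab <- paste0("b", b$blank_counter)
  b$blank_counter <- b$blank_counter + 1L
  node_blank(lab)
}

# Add one triple unless already present.  Subject: iri string or blank node.
builder_add <- function(b, s, p, o) {
  if (is.character(s)) s <- node_iri(s)
  if (is.character(o)) o <- node_iri(o)
  key <- paste(s$v, s$t, p, o$v, o$t, ifelse(is.na(o$dt), "", o$dt), sep = "\r")
  if (exists(key, envir = b$keys, inherits = FALSE)) return(invisible(FALSE))
  assign(key, TRUE, envir = b$keys)
  n <- b$n + 1L
  if (n > b$cap) {
    b$cap <- b$cap * 2L
    length(b$s) <- b$cap; length(b$s_type) <- b$cap; length(b$p) <- b$cap
    length(b$o) <- b$cap; length(b$o_type) <- b$cap; length(b$o_dt) <- b$cap
  }
  b$n <- n
  b$s[n] <- s$v; b$s_type[n] <- s$t; b$p[n] <- p
  b$o[n] <- o$v; b$o_type[n] <- o$t; b$o_dt[n] <- o$dt
  invisible(TRUE)
}

builder_has <- function(b, s, p, o) {
  if (is.character(s)) s <- node_iri(s)
  if (is.character(o)) o <- node_iri(o)
  key <- paste(s$v, s$t, p, o$v, o$t, ifelse(is.na(o$dt), "", o$dt), sep = "\r")
  exists(key, envir = b$keys, inherits = FALSE)
}

builder_freeze <- function(b) {
  n <- b$n
  new <- data.frame(s = b$s[seq_len(n)], s_type = b$s_type[seq_len(n)],
                    p = b$p[seq_len(n)], o = b$o[seq_len(n)],
                    o_type = b$o_type[seq_len(n)], o_dt = b$o_dt[seq_len(n)],
                    stringsAsFactors = FALSE)
  df <- rbind(b$base, new)
  rownames(df) <- NULL
  g <- list(triples = df, namespaces = b$namespaces, blank_counter = b$blank_counter)
  class(g) <- "ontology_graph"
  g
}

# ---- queries ---------------------------------------------------------------

#' Select triples matching a pattern
#'
#' `NULL` components act as wildcards.  Literal objects are matched on the
#' lexical form regardless of datatype.
#'
#' @param graph An `ontology_graph`.
#' @param s,p,o Subject / predicate / object to match, or `NULL`.
#' @return The matching rows of the triple data frame.
#' @export
graph_match <- function(graph, s = NULL, p = NULL, o = NULL) {
  df <- graph$triples
  keep <- rep(TRUE, nrow(df))
  if (!is.null(s)) keep <- keep & df$s == s
  if (!is.null(p)) keep <- keep & df$p == p
  if (!is.null(o)) keep <- keep & df$o == o
  df[keep, , drop = FALSE]
}

graph_contains <- function(graph, s, p, o, o_type = "iri") {
  df <- graph$triples
  any(df$s == s & df$p == p & df$o == o & df$o_type == o_type)
}

# Canonical row order used by every serializer: stable output for a fixed
# graph.  Blank subjects sort after IRI subjects.
canonical_order <- function(df) {
  ord <- order(df$s_type, df$s, df$p != RDF_TYPE, df$p,
               df$o_type, df$o, ifelse(is.na(df$o_dt), "", df$o_dt),
               method = "radix")
  df[ord, , drop = FALSE]
}

#' Merge namespace tables of a graph
#' @noRd
graph_add_namespace <- function(graph, prefix, iri) {
  graph$namespaces[[prefix]] <- iri
  graph
}
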