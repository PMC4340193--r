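# Serialization front end: syntax registry, dispatch, shared helpers.

syntax_table <- function() {
  c(rdfxml = "rdfxml", `rdfxml-abbrev` = "rdfxml-abbrev",
    turtle = "turtle", ntriples = "ntriples", n3 = "n3")
}

#' Supported serialization syntaxes
#'
#' The capability query: names accepted (case-insensitively) by
#' [serialize_graph()] and [parse_document()].
#'
#' @return Character vector of syntax names.
#' @export
supported_syntaxes <- function() unname(syntax_table())

resolve_syntax <- function(syntax) {
  s <- tolower(trimws(syntax))
  # tolerate common aliases
  aliases <- c("n-triple" = "ntriples", "n-triples" = "ntriples",
               "ttl" = "turtle", "nt" = "ntriples")
  if (s %in% names(aliases)) s <- unname(aliases[[s]])
  if (!(s %in% supported_syntaxes())) {
    stop("unsupported syntax '", syntax, "'; supported: ",
         paste(supported_syntaxes(), collapse = ", "), call. = FALSE)
  }
  s
}

#' Serialize an ontology graph
#'
#' Emits the graph in the named RDF syntax.  Output is deterministic for a
#' fixed graph and syntax: triples are emitted in a canonical order, so two
#' runs produce byte-identical documents.
#'
#' @param graph An `ontology_graph`.
#' @param syntax One of [supported_syntaxes()] (case-insensitive).
#' @return The document as a single UTF-8 string.
#' @examples
#' g <- map_structure(list(class_model("A")))
#' cat(substr(serialize_graph(g, "turtle"), 1, 80))
#' @export
serialize_graph <- function(graph, syntax = "rdfxml") {
  stopifnot(inherits(graph, "ontology_graph"))
  switch(resolve_syntax(syntax),
    ntriples         = emit_ntriples(graph),
    turtle           = emit_turtle(graph),
    n3               = emit_turtle(graph),  # emitted subset is valid N3
    rdfxml           = emit_rdfxml(graph, abbrev = FALSE),
    `rdfxml-abbrev`  = emit_rdfxml(graph, abbrev = TRUE)
  )
}

#' Parse an RDF document into an ontology graph
#'
#' Inverse of [serialize_graph()]: `parse_document(serialize_graph(g, s), s)`
#' is isomorphic to `g` for every supported syntax.
#'
#' @param text Document text (single string or character vector of lines).
#' @param syntax One of [supported_syntaxes()].
#' @return An `ontology_graph` containing exactly the document's triples.
#' @export
parse_document <- function(text, syntax) {
  text <- paste(text, collapse = "\n")
  switch(resolve_syntax(syntax),
    ntriples        = parse_ntriples(text),
    turtle          = parse_turtle(text),
    n3              = parse_turtle(text),
    rdfxml          = parse_rdfxml(text),
    `rdfxml-abbrev` = parse_rdfxml(text)
  )
}

# ---- shared name helpers ---------------------------------------------------

# Split an IRI at the last '#' or '/'; NULL when no split point.
split_iri <- function(iri) {
  m <- regexpr("[#/](?=[^#/]+$)", iri, perl = TRUE)
  if (m < 0) return(NULL)
  list(ns = substr(iri, 1L, m), local = substr(iri, m + 1L, nchar(iri)))
}

local_name_ok <- function(local) {
  grepl("^[A-Za-z_][A-Za-z0-9_-]*$", local)
}

# prefix:local when the namespace table allows it, else NULL.
qname_of <- function(iri, namespaces) {
  sp <- split_iri(iri)
  if (is.null(sp) || !local_name_ok(sp$local)) return(NULL)
  hit <- names(namespaces)[namespaces == sp$ns]
  if (length(hit) == 0L) return(NULL)
  paste0(hit[[1L]], ":", sp$local)
}

# Namespace table extended so every given IRI has a usable prefix.
ensure_prefixes <- function(iris, namespaces) {
  k <- 1L
  for (iri in iris) {
    sp <- split_iri(iri)
    if (is.null(sp) || !local_name_ok(sp$local)) {
      stop("cannot form a qualified name for IRI: ", iri, call. = FALSE)
    }
    if (!(sp$ns %in% namespaces)) {
      while (paste0("ns", k) %in% names(namespaces)) k <- k + 1L
      namespaces[[paste0("ns", k)]] <- sp$ns
    }
  }
  namespaces
}

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_literal <- function(x) {
  if (!grepl("\\", x, fixed = TRUE)) return(x)
  out <- character()
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[[i]]
    if (ch == "\\" && i < n) {
      nxt <- chars[[i + 1L]]
      rep <- switch(nxt, n = "\n", r = "\r", t = "\t", "\"" = "\"",
                    "\\" = "\\", "'" = "'", b = "\b", f = "\f", NULL)
      if (!is.null(rep)) {
        out <- c(out, rep); i <- i + 2L; next
      }
      if (nxt == "u" && i + 5L <= n) {
        code <- paste(chars[(i + 2L):(i + 5L)], collapse = "")
        out <- c(out, intToUtf8(strtoi(code, 16L))); i <- i + 6L; next
      }
      if (nxt == "U" && i + 9L <= n) {
        code <- paste(chars[(i + 2L):(i + 9L)], collapse = "")
        out <- c(out, intToUtf8(strtoi(code, 16L))); i <- i + 10L; next
      }
    }
    out <- c(out, ch); i <- i + 1L
  }
  paste(out, collapse = "")
}
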