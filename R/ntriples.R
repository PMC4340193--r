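# N-Triples emitter and parser (RDF 1.1 N-Triples, line-based).

nt_node <- function(v, t, dt) {
  if (t == "iri") return(paste0("<", v, ">"))
  if (t == "blank") return(paste0("_:", v))
  lit <- paste0("\"", escape_literal(v), "\"")
  if (!is.na(dt)) lit <- paste0(lit, "^^<", dt, ">")
  lit
}

emit_ntriples <- function(graph) {
  df <- canonical_order(graph$triples)
  if (nrow(df) == 0L) return("")
  subj <- ifelse(df$s_type == "blank", paste0("_:", df$s), paste0("<", df$s, ">"))
  pred <- paste0("<", df$p, ">")
  obj <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    obj[[i]] <- nt_node(df$o[[i]], df$o_type[[i]], df$o_dt[[i]])
  }
  paste0(paste(subj, pred, obj, "."), collapse = "\n")
}

parse_ntriples <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  g <- ontology_graph()
  b <- graph_builder(g)
  bmap <- new.env(parent = emptyenv())
  node_pat <- paste0(
    "\\s*(",
    "<[^>]*>",                            # IRI
    "|_:[A-Za-z0-9][A-Za-z0-9_.-]*",      # blank
    "|\"(?:[^\"\\\\]|\\\\.)*\"(?:\\^\\^<[^>]*>|@[A-Za-z0-9-]+)?",  # literal
    ")"
  )
  line_pat <- paste0("^", node_pat, node_pat, node_pat, "\\s*\\.\\s*$")

  to_node <- function(tok) {
    if (startsWith(tok, "<")) {
      node_iri(substr(tok, 2L, nchar(tok) - 1L))
    } else if (startsWith(tok, "_:")) {
      lab <- substr(tok, 3L, nchar(tok))
      if (!exists(lab, envir = bmap, inherits = FALSE)) {
        assign(lab, builder_fresh_blank(b), envir = bmap)
      }
      get(lab, envir = bmap)
    } else {
      m <- regmatches(tok, regexec(
        "^\"((?:[^\"\\\\]|\\\\.)*)\"(?:\\^\\^<([^>]*)>)?(?:@([A-Za-z0-9-]+))?$",
        tok, perl = TRUE))[[1L]]
      dt <- if (nzchar(m[[3L]])) m[[3L]] else NA_character_
      node_literal(unescape_literal(m[[2L]]), dt)
    }
  }

  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (grepl("^\\s*(#|$)", line)) next
    m <- regmatches(line, regexec(line_pat, line, perl = TRUE))[[1L]]
    if (length(m) == 0L) {
      stop("N-Triples parse error at line ", i, ": ", trimws(line), call. = FALSE)
    }
    s <- to_node(m[[2L]])
    p <- to_node(m[[3L]])
    if (p$t != "iri") stop("N-Triples parse error at line ", i,
                           ": predicate must be an IRI", call. = FALSE)
    builder_add(b, s, p$v, to_node(m[[4L]]))
  }
  builder_freeze(b)
}
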