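# RDF/XML emitter and parser, built on xml2 for the XML layer.
#
# Plain form: one rdf:Description element per subject.  Abbreviated form
# ("rdfxml-abbrev"): typed node elements named after the subject's rdf:type,
# with singly-referenced blank nodes nested inline inside their property
# element -- the style restriction superclasses are usually printed in.

rdfxml_ns_map <- function(graph) {
  iris <- unique(c(graph$triples$p,
                   graph$triples$o[graph$triples$o_type == "iri" &
                                   graph$triples$p == RDF_TYPE]))
  ensure_prefixes(iris, graph$namespaces)
}

xml_qname <- function(iri, ns) {
  q <- qname_of(iri, ns)
  if (is.null(q)) stop("cannot form an XML qualified name for IRI: ", iri,
                       call. = FALSE)
  q
}

emit_rdfxml <- function(graph, abbrev = FALSE) {
  ns <- rdfxml_ns_map(graph)
  df <- canonical_order(graph$triples)

  root <- xml2::xml_new_root("rdf:RDF")
  for (p in names(ns)) {
    xml2::xml_set_attr(root, paste0("xmlns:", p), ns[[p]])
  }

  subj_key <- paste0(df$s_type, "\r", df$s)
  rows_of <- split(seq_len(nrow(df)), factor(subj_key, levels = unique(subj_key)))

  # reference counts for blank nodes (abbrev inlining)
  blank_refs <- table(df$o[df$o_type == "blank"])
  inlined <- new.env(parent = emptyenv())

  emit_subject <- function(parent, rows, as_nested = FALSE) {
    s <- df$s[rows[[1L]]]; s_blank <- df$s_type[rows[[1L]]] == "blank"
    type_rows <- rows[df$p[rows] == RDF_TYPE & df$o_type[rows] == "iri"]
    elem_name <- "rdf:Description"
    if (abbrev && length(type_rows)) {
      q <- qname_of(df$o[type_rows[[1L]]], ns)
      if (!is.null(q)) {
        elem_name <- q
        rows <- setdiff(rows, type_rows[[1L]])
      }
    }
    node <- xml2::xml_add_child(parent, elem_name)
    if (!s_blank) {
      xml2::xml_set_attr(node, "rdf:about", s)
    } else if (!as_nested) {
      xml2::xml_set_attr(node, "rdf:nodeID", s)
    }
    for (i in rows) {
      pel <- xml2::xml_add_child(node, xml_qname(df$p[i], ns))
      ot <- df$o_type[i]
      if (ot == "iri") {
        xml2::xml_set_attr(pel, "rdf:resource", df$o[i])
      } else if (ot == "blank") {
        lab <- df$o[i]
        if (abbrev && blank_refs[[lab]] == 1L &&
            !exists(lab, envir = inlined, inherits = FALSE)) {
          assign(lab, TRUE, envir = inlined)
          child_rows <- rows_of[[paste0("blank\r", lab)]]
          if (!is.null(child_rows)) emit_subject(pel, child_rows, as_nested = TRUE)
          else xml2::xml_set_attr(pel, "rdf:nodeID", lab)
        } else {
          xml2::xml_set_attr(pel, "rdf:nodeID", lab)
        }
      } else {
        if (!is.na(df$o_dt[i])) xml2::xml_set_attr(pel, "rdf:datatype", df$o_dt[i])
        xml2::xml_set_text(pel, df$o[i])
      }
    }
    invisible(node)
  }

  for (sk in names(rows_of)) {
    if (abbrev) {
      lab <- sub("^(iri|blank)\r", "", sk)
      if (startsWith(sk, "blank") && lab %in% names(blank_refs) &&
          blank_refs[[lab]] == 1L) {
        next  # will be nested at its single point of reference
      }
    }
    emit_subject(root, rows_of[[sk]])
  }
  doc <- as.character(xml2::xml_root(root))
  doc
}

parse_rdfxml <- function(text) {
  doc <- xml2::read_xml(text, options = c("NOBLANKS", "NOENT"))
  ns <- xml2::xml_ns(doc)
  rdf_pfx <- names(ns)[ns == NS_RDF]
  if (length(rdf_pfx) == 0L) {
    stop("RDF/XML parse error: the rdf namespace is not declared", call. = FALSE)
  }
  rdf_pfx <- rdf_pfx[[1L]]
  rdf_attr <- function(node, local) {
    v <- xml2::xml_attr(node, paste0(rdf_pfx, ":", local), ns = ns)
    if (is.na(v)) NULL else v
  }
  base_iri <- xml2::xml_attr(doc, "xml:base")
  if (is.na(base_iri)) base_iri <- xml2::xml_attr(doc, "base")

  g <- ontology_graph()
  b <- graph_builder(g)
  bmap <- new.env(parent = emptyenv())
  doc_blank <- function(label) {
    if (!exists(label, envir = bmap, inherits = FALSE)) {
      assign(label, builder_fresh_blank(b), envir = bmap)
    }
    get(label, envir = bmap)
  }

  expand_name <- function(node) {
    # full IRI of a node's qualified element name
    nm <- xml2::xml_name(node, ns = ns)
    parts <- strsplit(nm, ":", fixed = TRUE)[[1L]]
    if (length(parts) == 2L && parts[[1L]] %in% names(ns)) {
      paste0(ns[[parts[[1L]]]], parts[[2L]])
    } else {
      stop("RDF/XML parse error: element '", nm, "' has no namespace",
           call. = FALSE)
    }
  }

  parse_node_elem <- function(elem) {
    about <- rdf_attr(elem, "about")
    id <- rdf_attr(elem, "ID")
    node_id <- rdf_attr(elem, "nodeID")
    subject <- if (!is.null(about)) {
      node_iri(about)
    } else if (!is.null(id)) {
      if (is.na(base_iri)) stop("RDF/XML parse error: rdf:ID without xml:base",
                                call. = FALSE)
      node_iri(paste0(sub("#$", "", base_iri), "#", id))
    } else if (!is.null(node_id)) {
      doc_blank(node_id)
    } else {
      builder_fresh_blank(b)
    }
    type_iri <- expand_name(elem)
    if (type_iri != rdf_iri("Description")) {
      builder_add(b, subject, RDF_TYPE, type_iri)
    }
    for (pel in xml2::xml_children(elem)) {
      parse_property_elem(subject, pel)
    }
    subject
  }

  parse_property_elem <- function(subject, pel) {
    pred <- expand_name(pel)
    res <- rdf_attr(pel, "resource")
    node_id <- rdf_attr(pel, "nodeID")
    dtype <- rdf_attr(pel, "datatype")
    ptype <- rdf_attr(pel, "parseType")
    kids <- xml2::xml_children(pel)
    if (!is.null(res)) {
      builder_add(b, subject, pred, node_iri(res))
    } else if (!is.null(node_id)) {
      builder_add(b, subject, pred, doc_blank(node_id))
    } else if (!is.null(ptype) && ptype == "Resource") {
      inner <- builder_fresh_blank(b)
      builder_add(b, subject, pred, inner)
      for (k in kids) parse_property_elem(inner, k)
    } else if (length(kids)) {
      obj <- parse_node_elem(kids[[1L]])
      builder_add(b, subject, pred, obj)
    } else {
      builder_add(b, subject, pred,
                  node_literal(xml2::xml_text(pel), dtype %||% NA_character_))
    }
  }

  for (child in xml2::xml_children(doc)) parse_node_elem(child)
  builder_freeze(b)
}
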