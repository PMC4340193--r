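# Turtle emitter and parser.  The emitter groups triples by subject with
# ';'/',' continuation and prefixed names; the parser is a tokenizer +
# recursive-descent reader covering the Turtle constructs the package emits
# plus the usual extras (anonymous blank nodes, collections, numeric and
# boolean shorthand, @base).  N3 documents produced here are the Turtle
# subset, which is valid N3.

ttl_name <- function(iri, namespaces) {
  q <- qname_of(iri, namespaces)
  if (is.null(q)) paste0("<", iri, ">") else q
}

ttl_object <- function(v, t, dt, namespaces) {
  if (t == "iri") return(ttl_name(v, namespaces))
  if (t == "blank") return(paste0("_:", v))
  lit <- paste0("\"", escape_literal(v), "\"")
  if (!is.na(dt)) lit <- paste0(lit, "^^", ttl_name(dt, namespaces))
  lit
}

emit_turtle <- function(graph) {
  ns <- graph$namespaces
  out <- sprintf("@prefix %s: <%s> .", names(ns)[order(names(ns))],
                 ns[order(names(ns))])
  df <- canonical_order(graph$triples)
  if (nrow(df)) {
    out <- c(out, "")
    subj_key <- paste0(df$s_type, "\r", df$s)
    for (sk in unique(subj_key)) {
      rows <- df[subj_key == sk, , drop = FALSE]
      subj <- if (rows$s_type[[1L]] == "blank") paste0("_:", rows$s[[1L]])
              else ttl_name(rows$s[[1L]], ns)
      stmts <- character()
      for (p in unique(rows$p)) {
        prows <- rows[rows$p == p, , drop = FALSE]
        pred <- if (p == RDF_TYPE) "a" else ttl_name(p, ns)
        objs <- vapply(seq_len(nrow(prows)), function(i) {
          ttl_object(prows$o[[i]], prows$o_type[[i]], prows$o_dt[[i]], ns)
        }, character(1))
        stmts <- c(stmts, paste(pred, paste(objs, collapse = " , ")))
      }
      out <- c(out, paste0(subj, " ", paste(stmts, collapse = " ;\n    "), " ."))
    }
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

# ---- parser ----------------------------------------------------------------

ttl_tokenize <- function(text) {
  pat <- paste0(
    "<[^<>\"{}|^`\\\\[:space:]]*>",                 # IRIREF
    "|\"\"\"(?s:.*?)\"\"\"",                        # long string
    "|\"(?:[^\"\\\\\\n]|\\\\.)*\"",                 # string
    "|'(?:[^'\\\\\\n]|\\\\.)*'",                    # single-quoted string
    "|_:[A-Za-z0-9][A-Za-z0-9_.-]*",                # blank node label
    "|@[A-Za-z][A-Za-z0-9-]*",                      # directive or langtag
    "|\\^\\^",
    "|[+-]?[0-9]+\\.[0-9]*(?:[eE][+-]?[0-9]+)?",    # decimal/double
    "|[+-]?\\.?[0-9]+(?:[eE][+-]?[0-9]+)?",         # integer/double
    "|(?:[A-Za-z_][A-Za-z0-9_.-]*)?:[A-Za-z0-9_]?[A-Za-z0-9_.-]*", # pname
    "|[A-Za-z_][A-Za-z0-9_.-]*",                    # bare word (a, true, PREFIX)
    "|#[^\\n]*",                                    # comment
    "|[.;,()\\[\\]]"
  )
  m <- gregexpr(pat, text, perl = TRUE)[[1L]]
  if (m[[1L]] == -1L) return(character())
  toks <- regmatches(text, list(m))[[1L]]
  # every character outside a token must be whitespace
  covered <- rep(FALSE, nchar(text))
  for (i in seq_along(m)) {
    covered[seq(m[[i]], length.out = attr(m, "match.length")[[i]])] <- TRUE
  }
  leftover <- substring(text, which(!covered), which(!covered))
  if (any(!grepl("^[[:space:]]$", leftover))) {
    bad <- which(!covered)[!grepl("^[[:space:]]$", leftover)][[1L]]
    stop("Turtle parse error: unexpected character at offset ", bad, call. = FALSE)
  }
  toks[!startsWith(toks, "#")]
}

parse_turtle <- function(text) {
  toks <- ttl_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$i <- 1L
  st$prefixes <- character(); st$base <- ""
  st$bmap <- new.env(parent = emptyenv())
  g <- ontology_graph()
  st$b <- graph_builder(g)

  peek <- function() if (st$i <= length(st$toks)) st$toks[[st$i]] else NA_character_
  advance <- function() { tok <- peek(); st$i <- st$i + 1L; tok }
  expect <- function(tok) {
    got <- advance()
    if (is.na(got) || got != tok) {
      stop("Turtle parse error: expected '", tok, "' at token ", st$i - 1L,
           if (!is.na(got)) paste0(", got '", got, "'") else ", got end of input",
           call. = FALSE)
    }
  }

  resolve_iriref <- function(tok) {
    iri <- substr(tok, 2L, nchar(tok) - 1L)
    iri <- unescape_literal(iri)
    if (!grepl("^[A-Za-z][A-Za-z0-9+.-]*:", iri) && nzchar(st$base)) {
      iri <- paste0(st$base, iri)
    }
    iri
  }
  resolve_pname <- function(tok) {
    i <- regexpr(":", tok, fixed = TRUE)
    pfx <- substr(tok, 1L, i - 1L)
    local <- substr(tok, i + 1L, nchar(tok))
    key <- if (nzchar(pfx)) pfx else "%default%"
    if (!(key %in% names(st$prefixes))) {
      stop("Turtle parse error: undeclared prefix '", pfx, ":'", call. = FALSE)
    }
    node_iri(paste0(st$prefixes[[key]], local))
  }
  doc_blank <- function(label) {
    if (!exists(label, envir = st$bmap, inherits = FALSE)) {
      assign(label, builder_fresh_blank(st$b), envir = st$bmap)
    }
    get(label, envir = st$bmap)
  }

  is_string_tok <- function(tok) startsWith(tok, "\"") || startsWith(tok, "'")
  string_value <- function(tok) {
    if (startsWith(tok, "\"\"\"")) {
      unescape_literal(substr(tok, 4L, nchar(tok) - 3L))
    } else {
      unescape_literal(substr(tok, 2L, nchar(tok) - 1L))
    }
  }

  parse_literal <- function(tok) {
    val <- string_value(tok)
    nxt <- peek()
    if (!is.na(nxt) && nxt == "^^") {
      advance()
      dt_tok <- advance()
      dt <- if (startsWith(dt_tok, "<")) resolve_iriref(dt_tok)
            else resolve_pname(dt_tok)$v
      node_literal(val, dt)
    } else if (!is.na(nxt) && grepl("^@[A-Za-z]", nxt) &&
               !(nxt %in% c("@prefix", "@base"))) {
      advance()  # language tag: kept out of the value model
      node_literal(val)
    } else {
      node_literal(val)
    }
  }

  parse_collection <- function() {
    members <- list()
    while (!is.na(peek()) && peek() != ")") members[[length(members) + 1L]] <- parse_object()
    expect(")")
    builder_add_list(st$b, members)
  }

  parse_blank_props <- function() {
    node <- builder_fresh_blank(st$b)
    if (!is.na(peek()) && peek() != "]") parse_predicate_object_list(node)
    expect("]")
    node
  }

  parse_object <- function() {
    tok <- advance()
    if (is.na(tok)) stop("Turtle parse error: unexpected end of input", call. = FALSE)
    if (startsWith(tok, "<")) return(node_iri(resolve_iriref(tok)))
    if (startsWith(tok, "_:")) return(doc_blank(substr(tok, 3L, nchar(tok))))
    if (is_string_tok(tok)) return(parse_literal(tok))
    if (tok == "(") return(parse_collection())
    if (tok == "[") return(parse_blank_props())
    if (tok %in% c("true", "false")) return(node_literal(tok, XSD_BOOLEAN))
    if (grepl("^[+-]?[0-9.]", tok)) {
      dt <- if (grepl("[eE]", tok)) XSD_DOUBLE
            else if (grepl("\\.", tok)) xsd_iri("decimal")
            else XSD_INTEGER
      return(node_literal(tok, dt))
    }
    if (grepl(":", tok, fixed = TRUE)) return(resolve_pname(tok))
    stop("Turtle parse error: unexpected token '", tok, "'", call. = FALSE)
  }

  parse_verb <- function() {
    tok <- advance()
    if (identical(tok, "a")) return(RDF_TYPE)
    if (is.na(tok)) stop("Turtle parse error: unexpected end of input", call. = FALSE)
    if (startsWith(tok, "<")) return(resolve_iriref(tok))
    if (grepl(":", tok, fixed = TRUE)) return(resolve_pname(tok)$v)
    stop("Turtle parse error: expected predicate, got '", tok, "'", call. = FALSE)
  }

  parse_predicate_object_list <- function(subject) {
    repeat {
      p <- parse_verb()
      repeat {
        builder_add(st$b, subject, p, parse_object())
        if (identical(peek(), ",")) advance() else break
      }
      if (identical(peek(), ";")) {
        advance()
        # tolerate trailing ';' before '.' or ']'
        if (is.na(peek()) || peek() %in% c(".", "]")) break
      } else break
    }
  }

  while (!is.na(peek())) {
    tok <- peek()
    if (tok == "@prefix" || toupper(tok) == "PREFIX") {
      advance()
      pn <- advance()
      if (!grepl(":$", pn)) stop("Turtle parse error: bad prefix declaration",
                                 call. = FALSE)
      iri_tok <- advance()
      pfx <- substr(pn, 1L, nchar(pn) - 1L)
      st$prefixes[[if (nzchar(pfx)) pfx else "%default%"]] <- resolve_iriref(iri_tok)
      if (identical(peek(), ".")) advance()
    } else if (tok == "@base" || toupper(tok) == "BASE") {
      advance()
      st$base <- resolve_iriref(advance())
      if (identical(peek(), ".")) advance()
    } else {
      subject <- if (tok == "[") { advance(); parse_blank_props() }
                 else if (tok == "(") { advance(); parse_collection() }
                 else parse_object()
      if (subject$t == "literal") {
        stop("Turtle parse error: literal cannot be a subject", call. = FALSE)
      }
      parse_predicate_object_list(subject)
      expect(".")
    }
  }
  builder_freeze(st$b)
}
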