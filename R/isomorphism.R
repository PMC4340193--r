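# RDF graph isomorphism: equality of triple sets up to a bijective renaming
# of blank nodes.  Ground triples are compared directly; blank nodes are
# partitioned by iterative signature refinement and the remaining ambiguity
# resolved by backtracking inside the refined classes.

triple_key_df <- function(df) {
  paste(df$s_type, df$s, df$p, df$o_type, df$o,
        ifelse(is.na(df$o_dt), "", df$o_dt), sep = "\r")
}

normalize_triples <- function(df) {
  # plain literal == xsd:string (node_literal enforces this on construction,
  # but graphs may arrive from external parsers)
  df$o_dt[!is.na(df$o_dt) & df$o_dt == XSD_STRING & df$o_type == "literal"] <-
    NA_character_
  df[!duplicated(triple_key_df(df)), , drop = FALSE]
}

blank_signatures <- function(df, colors) {
  # one refinement round: each blank's color becomes the multiset of its
  # incident triple shapes, with neighbouring blanks abstracted to colors
  labs <- names(colors)
  sigs <- stats::setNames(character(length(labs)), labs)
  s_blank <- df$s_type == "blank"
  o_blank <- df$o_type == "blank"
  for (lab in labs) {
    out_rows <- which(s_blank & df$s == lab)
    in_rows <- which(o_blank & df$o == lab)
    parts <- c(
      vapply(out_rows, function(i) {
        obj <- if (o_blank[i]) paste0("~", colors[[df$o[i]]])
               else paste0(df$o_type[i], ":", df$o[i], ":",
                           ifelse(is.na(df$o_dt[i]), "", df$o_dt[i]))
        paste0("OUT|", df$p[i], "|", obj)
      }, character(1)),
      vapply(in_rows, function(i) {
        subj <- if (s_blank[i]) paste0("~", colors[[df$s[i]]])
                else paste0("iri:", df$s[i])
        paste0("IN|", df$p[i], "|", subj)
      }, character(1))
    )
    sigs[[lab]] <- paste(sort(parts), collapse = "\n")
  }
  # compress to small color ids (stable across graphs: sort by signature)
  uniq <- sort(unique(sigs))
  stats::setNames(match(sigs, uniq), labs)
}

refine_colors <- function(df) {
  labs <- unique(c(df$s[df$s_type == "blank"], df$o[df$o_type == "blank"]))
  if (length(labs) == 0L) return(stats::setNames(integer(), character()))
  colors <- stats::setNames(rep(1L, length(labs)), labs)
  repeat {
    nxt <- blank_signatures(df, colors)
    if (length(unique(nxt)) == length(unique(colors))) {
      # stable partition (signature ids are recomputed each round, so compare
      # class counts and memberships)
      same <- all(vapply(split(names(colors), colors), function(cls) {
        length(unique(nxt[cls])) == 1L
      }, logical(1)))
      if (same) return(nxt)
    }
    colors <- nxt
  }
}

# color signature that is comparable across two graphs
color_class_key <- function(df, colors) {
  # recompute the textual signature of each color class once colors are stable
  labs <- names(colors)
  sigs <- blank_sig_text(df, colors)
  vapply(split(labs, colors), function(cls) sigs[[cls[[1L]]]], character(1))
}

blank_sig_text <- function(df, colors) {
  labs <- names(colors)
  sigs <- stats::setNames(character(length(labs)), labs)
  s_blank <- df$s_type == "blank"
  o_blank <- df$o_type == "blank"
  # use canonical per-color text: color -> rank by its own signature
  for (lab in labs) {
    out_rows <- which(s_blank & df$s == lab)
    in_rows <- which(o_blank & df$o == lab)
    parts <- c(
      vapply(out_rows, function(i) {
        obj <- if (o_blank[i]) paste0("~c", colors[[df$o[i]]])
               else paste0(df$o_type[i], ":", df$o[i], ":",
                           ifelse(is.na(df$o_dt[i]), "", df$o_dt[i]))
        paste0("OUT|", df$p[i], "|", obj)
      }, character(1)),
      vapply(in_rows, function(i) {
        subj <- if (s_blank[i]) paste0("~c", colors[[df$s[i]]])
                else paste0("iri:", df$s[i])
        paste0("IN|", df$p[i], "|", subj)
      }, character(1))
    )
    sigs[[lab]] <- paste(sort(parts), collapse = "\n")
  }
  sigs
}

#' Test two graphs for RDF isomorphism
#'
#' True iff the graphs contain the same triples up to a consistent renaming
#' of blank nodes.  This is the correctness notion under which all supported
#' serialization syntaxes are functionally equivalent.
#'
#' @param g1,g2 `ontology_graph` objects.
#' @return `TRUE` or `FALSE`.
#' @examples
#' g <- map_structure(list(class_model("A")))
#' graphs_isomorphic(g, g)
#' @export
graphs_isomorphic <- function(g1, g2) {
  stopifnot(inherits(g1, "ontology_graph"), inherits(g2, "ontology_graph"))
  d1 <- normalize_triples(g1$triples)
  d2 <- normalize_triples(g2$triples)
  if (nrow(d1) != nrow(d2)) return(FALSE)

  ground1 <- d1$s_type != "blank" & d1$o_type != "blank"
  ground2 <- d2$s_type != "blank" & d2$o_type != "blank"
  if (sum(ground1) != sum(ground2)) return(FALSE)
  if (!setequal(triple_key_df(d1[ground1, ]), triple_key_df(d2[ground2, ]))) {
    return(FALSE)
  }

  b1 <- d1[!ground1, , drop = FALSE]
  b2 <- d2[!ground2, , drop = FALSE]
  c1 <- refine_colors(d1)
  c2 <- refine_colors(d2)
  if (length(c1) != length(c2)) return(FALSE)
  if (length(c1) == 0L) return(TRUE)

  k1 <- color_class_key(d1, c1)
  k2 <- color_class_key(d2, c2)
  if (!identical(sort(unname(k1)), sort(unname(k2)))) return(FALSE)
  cls1 <- split(names(c1), c1)
  cls2 <- split(names(c2), c2)
  # align classes of g2 to classes of g1 by signature text
  align <- match(unname(k1), unname(k2))
  if (anyNA(align)) return(FALSE)
  for (i in seq_along(cls1)) {
    if (length(cls1[[i]]) != length(cls2[[align[[i]]]]) ) return(FALSE)
  }

  # backtracking assignment, verified against g2's blank-triple key set
  keyset2 <- new.env(parent = emptyenv())
  for (k in triple_key_df(b2)) assign(k, TRUE, envir = keyset2)

  order1 <- unlist(cls1, use.names = FALSE)
  class_of <- rep(seq_along(cls1), lengths(cls1))
  mapping <- new.env(parent = emptyenv())
  used <- new.env(parent = emptyenv())

  consistent <- function(lab) {
    # all b1 triples touching lab whose blanks are fully mapped must be in b2
    rows <- which((b1$s_type == "blank" & b1$s == lab) |
                  (b1$o_type == "blank" & b1$o == lab))
    for (i in rows) {
      s <- b1$s[i]; o <- b1$o[i]
      if (b1$s_type[i] == "blank") {
        if (!exists(s, envir = mapping, inherits = FALSE)) next
        s <- get(s, envir = mapping)
      }
      if (b1$o_type[i] == "blank") {
        if (!exists(o, envir = mapping, inherits = FALSE)) next
        o <- get(o, envir = mapping)
      }
      key <- paste(b1$s_type[i], s, b1$p[i], b1$o_type[i], o,
                   ifelse(is.na(b1$o_dt[i]), "", b1$o_dt[i]), sep = "\r")
      if (!exists(key, envir = keyset2, inherits = FALSE)) return(FALSE)
    }
    TRUE
  }

  assign_next <- function(pos) {
    if (pos > length(order1)) return(TRUE)
    lab <- order1[[pos]]
    candidates <- cls2[[align[[class_of[[pos]]]]]]
    for (cand in candidates) {
      if (exists(cand, envir = used, inherits = FALSE)) next
      assign(lab, cand, envir = mapping)
      assign(cand, TRUE, envir = used)
      if (consistent(lab) && assign_next(pos + 1L)) return(TRUE)
      rm(list = lab, envir = mapping)
      rm(list = cand, envir = used)
    }
    FALSE
  }

  assign_next(1L)
}
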