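# Object model -> OWL ontology graph.
#
# map_structure  : classes, inheritance, enumerations, properties
# map_instances  : records -> named, typed individuals with assertions
# apply_semantics: annotation markers -> the corresponding OWL constructs,
#                  value/cardinality constraints as anonymous restriction
#                  superclasses of the declaring class

stop_if_invalid <- function(classes, instances = list()) {
  rep <- validate_model(classes, instances)
  if (nrow(rep)) {
    head_msgs <- utils::head(rep$message, 3L)
    stop("model does not validate (", nrow(rep), " violation",
         if (nrow(rep) > 1L) "s" else "", "): ",
         paste(head_msgs, collapse = "; "), call. = FALSE)
  }
  invisible(TRUE)
}

mapper_namespaces <- function(cfg) {
  c(default_namespaces(),
    semantic = cfg$semantic_ns,
    this = cfg$base_iri)
}

# Emit an RDF list of nodes; returns the head node (rdf:nil for empty).
builder_add_list <- function(b, members) {
  if (length(members) == 0L) return(node_iri(RDF_NIL))
  head <- builder_fresh_blank(b)
  cell <- head
  for (i in seq_along(members)) {
    builder_add(b, cell, RDF_FIRST, members[[i]])
    if (i < length(members)) {
      nxt <- builder_fresh_blank(b)
      builder_add(b, cell, RDF_REST, nxt)
      cell <- nxt
    } else {
      builder_add(b, cell, RDF_REST, node_iri(RDF_NIL))
    }
  }
  head
}

#' Map model structure to an ontology graph
#'
#' Implements the structural half of the transformation: every class becomes
#' an `owl:Class` annotated with its qualified source name, inheritance
#' becomes `rdfs:subClassOf`, atomic fields become `owl:DatatypeProperty`
#' nodes with XSD ranges, reference and collection fields become
#' `owl:ObjectProperty` nodes, and enumerations become classes equivalent to
#' an `owl:oneOf` list of one individual per literal.
#'
#' OWL properties are global: when several classes declare the same field
#' name with an identical range, one property is emitted whose domain is an
#' `owl:unionOf` class of the declaring classes; conflicting ranges are an
#' error.
#'
#' @param classes List of [class_model()] objects; must validate.
#' @param cfg A [mapping_config()].
#' @return An `ontology_graph`.
#' @examples
#' m <- list(class_model("Person", "cz.zcu.kiv.Person", fields = list(
#'   field_model("firstname", "atomic", atomic_kind = "string"))))
#' g <- map_structure(m)
#' @export
map_structure <- function(classes, cfg = mapping_config()) {
  stop_if_invalid(classes)
  g <- ontology_graph(namespaces = mapper_namespaces(cfg))
  b <- graph_builder(g)
  builder_add(b, ontology_iri(cfg), RDF_TYPE, OWL_ONTOLOGY)

  minted <- new.env(parent = emptyenv())
  claim_iri <- function(iri, what) {
    prev <- if (exists(iri, envir = minted, inherits = FALSE)) get(iri, envir = minted) else NULL
    if (!is.null(prev) && !identical(prev, what)) {
      stop("IRI collision: ", iri, " minted for both ", prev, " and ", what,
           call. = FALSE)
    }
    assign(iri, what, envir = minted)
  }

  src_prop <- source_annotation_iri(cfg)

  for (cl in classes) {
    cls_iri <- mint_iri("class", cl$simple_name, cfg)
    claim_iri(cls_iri, paste0("class ", cl$simple_name))
    builder_add(b, cls_iri, RDF_TYPE, OWL_CLASS)
    builder_add(b, cls_iri, src_prop, node_literal(cl$qualified_name))
    if (!is.null(cl$superclass)) {
      builder_add(b, cls_iri, RDFS_SUBCLASSOF,
                  mint_iri("class", cl$superclass, cfg))
    }
    if (isTRUE(cl$is_enumeration)) {
      members <- lapply(cl$enum_literals, function(lit) {
        ind <- mint_iri("individual", c(cl$simple_name, lit), cfg)
        claim_iri(ind, paste0("enum literal ", cl$simple_name, ".", lit))
        builder_add(b, ind, RDF_TYPE, cls_iri)
        node_iri(ind)
      })
      one_of_cls <- builder_fresh_blank(b)
      builder_add(b, one_of_cls, RDF_TYPE, OWL_CLASS)
      builder_add(b, one_of_cls, OWL_ONE_OF, builder_add_list(b, members))
      builder_add(b, cls_iri, OWL_EQUIVALENT_CLASS, one_of_cls)
    }
  }

  # global property table: field name -> range signature + declaring domains
  props <- list()
  for (cl in classes) {
    for (f in cl$fields) {
      rng <- if (f$kind == "atomic") {
        list(type = OWL_DATATYPE_PROPERTY, range = atomic_to_datatype(f$atomic_kind))
      } else {
        list(type = OWL_OBJECT_PROPERTY,
             range = mint_iri("class", f$target_class, cfg))
      }
      entry <- props[[f$name]]
      if (is.null(entry)) {
        props[[f$name]] <- c(rng, list(domains = mint_iri("class", cl$simple_name, cfg)))
      } else {
        if (!identical(entry$type, rng$type) || !identical(entry$range, rng$range)) {
          stop("field '", f$name, "' declared with conflicting ranges; ",
               "OWL properties are global", call. = FALSE)
        }
        entry$domains <- union(entry$domains, mint_iri("class", cl$simple_name, cfg))
        props[[f$name]] <- entry
      }
    }
  }
  for (nm in names(props)) {
    p <- props[[nm]]
    prop_iri <- mint_iri("property", nm, cfg)
    claim_iri(prop_iri, paste0("property ", nm))
    builder_add(b, prop_iri, RDF_TYPE, p$type)
    if (length(p$domains) == 1L) {
      builder_add(b, prop_iri, RDFS_DOMAIN, p$domains)
    } else {
      u <- builder_fresh_blank(b)
      builder_add(b, u, RDF_TYPE, OWL_CLASS)
      builder_add(b, u, OWL_UNION_OF,
                  builder_add_list(b, lapply(sort(p$domains), node_iri)))
      builder_add(b, prop_iri, RDFS_DOMAIN, u)
    }
    builder_add(b, prop_iri, RDFS_RANGE, p$range)
  }
  builder_freeze(b)
}

format_atomic_literal <- function(val, datatype) {
  if (is.list(val)) val <- val[[1L]]
  lex <- if (identical(datatype, XSD_BOOLEAN)) {
    if (isTRUE(val) || identical(val, "true")) "true" else "false"
  } else if (identical(datatype, XSD_INTEGER)) {
    sprintf("%d", as.integer(val))
  } else if (identical(datatype, XSD_DOUBLE)) {
    format(as.numeric(val), scientific = FALSE, trim = TRUE, digits = 15)
  } else if (identical(datatype, XSD_DATE)) {
    if (inherits(val, "Date")) format(val, "%Y-%m-%d") else as.character(val)
  } else if (identical(datatype, XSD_DATETIME)) {
    if (inherits(val, "POSIXt")) format(val, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    else as.character(val)
  } else {
    as.character(val)
  }
  node_literal(lex, datatype)
}

#' Map instance records to OWL individuals
#'
#' Adds one named individual per record, typed by its class, with
#' datatype-property assertions for atomic values and object-property
#' assertions for references (including reference cycles, which do not
#' duplicate individuals).  Individual IRIs follow
#' `cfg$individual_naming`: sequential (`Person_0`, `Person_1`, ... per
#' class, in record order) or the value of the class's identifier field.
#'
#' @param graph Graph already holding the structural mapping of the records'
#'   classes (see [map_structure()]).
#' @param instances List of [instance_record()] objects.
#' @param cfg A [mapping_config()].
#' @param classes The class models; required for identifier-field naming,
#'   otherwise optional (property types and ranges are read off the graph).
#' @return The enlarged `ontology_graph`.
#' @export
map_instances <- function(graph, instances, cfg = mapping_config(),
                          classes = NULL) {
  if (!is.null(classes)) stop_if_invalid(classes, instances)
  b <- graph_builder(graph)
  df <- graph$triples

  # property metadata read off the structural graph, indexed once
  ptab <- new.env(parent = emptyenv())
  trows <- df$p == RDF_TYPE & df$o_type == "iri" &
           df$o %in% c(OWL_DATATYPE_PROPERTY, OWL_OBJECT_PROPERTY)
  for (i in which(trows)) {
    assign(df$s[i],
           if (df$o[i] == OWL_DATATYPE_PROPERTY) "datatype" else "object",
           envir = ptab)
  }
  rtab <- new.env(parent = emptyenv())
  for (i in which(df$p == RDFS_RANGE & df$o_type == "iri")) {
    assign(df$s[i], df$o[i], envir = rtab)
  }
  prop_type <- function(prop_iri) {
    if (exists(prop_iri, envir = ptab, inherits = FALSE)) get(prop_iri, envir = ptab)
    else NA_character_
  }
  prop_range <- function(prop_iri) {
    if (exists(prop_iri, envir = rtab, inherits = FALSE)) get(prop_iri, envir = rtab)
    else NA_character_
  }

  id_field <- function(class_name) {
    if (is.null(classes)) return(NULL)
    idx <- model_index(classes)
    for (f in effective_fields(class_name, idx)) {
      if (isTRUE(f$is_identifier)) return(f$name)
    }
    NULL
  }

  # pass 1: mint every individual IRI so cycles resolve
  counters <- new.env(parent = emptyenv())
  iri_of <- new.env(parent = emptyenv())
  minted <- new.env(parent = emptyenv())
  for (inst in instances) {
    cls_iri <- mint_iri("class", inst$class_name, cfg)
    if (!graph_contains(graph, cls_iri, RDF_TYPE, OWL_CLASS)) {
      stop("instance '", inst$local_id, "' is of class '", inst$class_name,
           "' which is absent from the graph", call. = FALSE)
    }
    suffix <- NULL
    if (cfg$individual_naming == "identifier-field") {
      idf <- id_field(inst$class_name)
      if (!is.null(idf) && idf %in% names(inst$values)) {
        suffix <- as.character(inst$values[[idf]])
      }
    }
    if (is.null(suffix)) {
      k <- if (exists(inst$class_name, envir = counters, inherits = FALSE)) {
        get(inst$class_name, envir = counters)
      } else 0L
      assign(inst$class_name, k + 1L, envir = counters)
      suffix <- as.character(k)
    }
    ind <- mint_iri("individual", c(inst$class_name, suffix), cfg)
    if (exists(ind, envir = minted, inherits = FALSE)) {
      stop("individual IRI collision while minting: ", ind, call. = FALSE)
    }
    assign(ind, TRUE, envir = minted)
    assign(inst$local_id, ind, envir = iri_of)
  }

  # pass 2: emit type + value assertions
  for (inst in instances) {
    ind <- get(inst$local_id, envir = iri_of)
    builder_add(b, ind, RDF_TYPE, mint_iri("class", inst$class_name, cfg))
    for (nm in names(inst$values)) {
      val <- inst$values[[nm]]
      if (is.null(val)) next  # absent value: no assertion
      prop_iri <- mint_iri("property", nm, cfg)
      pt <- prop_type(prop_iri)
      if (is.na(pt)) {
        stop("no property '", nm, "' in the structural graph (instance '",
             inst$local_id, "')", call. = FALSE)
      }
      if (pt == "datatype") {
        builder_add(b, ind, prop_iri,
                    format_atomic_literal(val, prop_range(prop_iri)))
      } else {
        rng <- prop_range(prop_iri)
        for (ref in as.character(unlist(val, use.names = FALSE))) {
          obj <- if (exists(ref, envir = iri_of, inherits = FALSE)) {
            get(ref, envir = iri_of)
          } else {
            # enumeration literal: the individual was minted with the structure
            cand <- paste0(rng, "_", ref)
            if (!graph_contains(graph, cand, RDF_TYPE, rng)) {
              stop("value '", ref, "' of field '", nm,
                   "' resolves to neither an instance nor an enumeration literal",
                   call. = FALSE)
            }
            cand
          }
          builder_add(b, ind, prop_iri, obj)
        }
      }
    }
  }
  builder_freeze(b)
}

restriction_markers <- function() {
  c("AllValuesFrom", "SomeValuesFrom", "Cardinality", "MinCardinality",
    "MaxCardinality")
}

restriction_predicate <- function(marker) {
  switch(marker,
    AllValuesFrom  = OWL_ALL_VALUES_FROM,
    SomeValuesFrom = OWL_SOME_VALUES_FROM,
    Cardinality    = OWL_CARDINALITY,
    MinCardinality = OWL_MIN_CARDINALITY,
    MaxCardinality = OWL_MAX_CARDINALITY,
    stop("not a restriction marker: ", marker)
  )
}

# Signature of a restriction: makes apply_semantics idempotent even though
# restrictions are blank nodes.
restriction_sig <- function(cls_iri, prop_iri, pred, objkey) {
  paste(cls_iri, prop_iri, pred, objkey, sep = "\r")
}

existing_restriction_sigs <- function(df) {
  sigs <- character()
  rblanks <- df$s[df$s_type == "blank" & df$p == RDF_TYPE &
                  df$o == OWL_RESTRICTION & df$o_type == "iri"]
  for (bl in unique(rblanks)) {
    props <- df$o[df$s == bl & df$p == OWL_ON_PROPERTY]
    crows <- df[df$s == bl & df$p %in% c(OWL_ALL_VALUES_FROM, OWL_SOME_VALUES_FROM,
                                         OWL_CARDINALITY, OWL_MIN_CARDINALITY,
                                         OWL_MAX_CARDINALITY), , drop = FALSE]
    supers <- df$s[df$p == RDFS_SUBCLASSOF & df$o == bl & df$o_type == "blank"]
    for (i in seq_len(nrow(crows))) {
      objkey <- if (crows$o_type[i] == "blank") {
        data_range_key(df, crows$o[i])
      } else {
        paste0(crows$o_type[i], ":", crows$o[i])
      }
      for (cls in supers) for (pp in props) {
        sigs <- c(sigs, restriction_sig(cls, pp, crows$p[i], objkey))
      }
    }
  }
  sigs
}

data_range_key <- function(df, blank) {
  # follow oneOf list of a DataRange blank node
  head <- df$o[df$s == blank & df$p == OWL_ONE_OF]
  vals <- character()
  while (length(head) && head != RDF_NIL) {
    vals <- c(vals, df$o[df$s == head & df$p == RDF_FIRST])
    head <- df$o[df$s == head & df$p == RDF_REST]
  }
  paste0("datarange:", paste(vals, collapse = "\x1f"))
}

build_restriction_on <- function(b, df, sigs, cls_iri, prop_iri, a, cfg) {
  pred <- restriction_predicate(a$marker)
  is_card <- a$marker %in% c("Cardinality", "MinCardinality", "MaxCardinality")
  if (is_card) {
    if (is.null(a$number) || a$number < 0L) {
      stop("cardinality marker requires a non-negative integer", call. = FALSE)
    }
    obj <- node_literal(sprintf("%d", a$number), cfg$cardinality_datatype)
    objkey <- paste0("literal:", obj$v)
  } else if (!is.null(a$resource)) {
    obj <- node_iri(a$resource)
    objkey <- paste0("iri:", a$resource)
  } else {
    obj <- NULL  # DataRange, built below
    objkey <- paste0("datarange:", paste(a$string_values, collapse = "\x1f"))
  }
  sig <- restriction_sig(cls_iri, prop_iri, pred, objkey)
  if (sig %in% sigs$seen) return(sigs)
  sigs$seen <- c(sigs$seen, sig)

  r <- builder_fresh_blank(b)
  builder_add(b, r, RDF_TYPE, OWL_RESTRICTION)
  builder_add(b, r, OWL_ON_PROPERTY, prop_iri)
  if (is.null(obj)) {
    dr <- builder_fresh_blank(b)
    builder_add(b, dr, RDF_TYPE, OWL_DATA_RANGE)
    builder_add(b, dr, OWL_ONE_OF,
                builder_add_list(b, lapply(a$string_values, node_literal)))
    builder_add(b, r, pred, dr)
  } else {
    builder_add(b, r, pred, obj)
  }
  builder_add(b, cls_iri, RDFS_SUBCLASSOF, r)
  sigs
}

#' Apply semantic annotations to a mapped graph
#'
#' Transforms every marker carried by the model into its OWL construct:
#' `EquivalentClass` -> `owl:equivalentClass`, `EquivalentProperty` ->
#' `owl:equivalentProperty`, `Symmetric`/`Transitive` -> an `rdf:type` of the
#' corresponding property class, `Inverse` -> `owl:inverseOf`, `SameAs` ->
#' `owl:sameAs`, `DifferentFrom` -> `owl:differentFrom`, `AllDifferent` ->
#' an `rdf:type` of the referenced resource, and the value/cardinality
#' markers (`AllValuesFrom`, `SomeValuesFrom`, `Cardinality`,
#' `MinCardinality`, `MaxCardinality`) -> anonymous `owl:Restriction`
#' superclasses of the declaring class.
#'
#' Re-applying to an already enriched graph adds no triples.
#'
#' @param graph Graph holding the structural mapping of `classes`.
#' @param classes List of [class_model()] objects; must validate.
#' @param cfg A [mapping_config()].
#' @return The enriched `ontology_graph`.
#' @export
apply_semantics <- function(graph, classes, cfg = mapping_config()) {
  stop_if_invalid(classes)
  b <- graph_builder(graph)
  df <- graph$triples
  sigs <- new.env(parent = emptyenv())
  sigs$seen <- existing_restriction_sigs(df)

  for (cl in classes) {
    cls_iri <- mint_iri("class", cl$simple_name, cfg)
    if (!graph_contains(graph, cls_iri, RDF_TYPE, OWL_CLASS)) {
      stop("class '", cl$simple_name, "' is absent from the graph; ",
           "run map_structure first", call. = FALSE)
    }
    for (a in cl$annotations) {
      switch(a$marker,
        EquivalentClass = {
          builder_add(b, a$resource, RDF_TYPE, OWL_CLASS)
          builder_add(b, cls_iri, OWL_EQUIVALENT_CLASS, a$resource)
        },
        SameAs        = builder_add(b, cls_iri, OWL_SAME_AS, a$resource),
        DifferentFrom = builder_add(b, cls_iri, OWL_DIFFERENT_FROM, a$resource),
        AllDifferent  = builder_add(b, cls_iri, RDF_TYPE, a$resource),
        stop("marker '", a$marker, "' is not a class-level marker", call. = FALSE)
      )
    }
    for (f in cl$fields) {
      if (length(f$annotations) == 0L) next
      prop_iri <- mint_iri("property", f$name, cfg)
      for (a in f$annotations) {
        if (a$marker %in% c("Symmetric", "Transitive", "Inverse") &&
            identical(f$kind, "atomic")) {
          stop("marker '", a$marker, "' on atomic field '", f$name,
               "': object-property-only construct", call. = FALSE)
        }
        if (a$marker %in% restriction_markers()) {
          build_restriction_on(b, df, sigs, cls_iri, prop_iri, a, cfg)
        } else {
          switch(a$marker,
            EquivalentProperty =
              builder_add(b, prop_iri, OWL_EQUIVALENT_PROP, a$resource),
            Symmetric  = builder_add(b, prop_iri, RDF_TYPE, OWL_SYMMETRIC_PROPERTY),
            Transitive = builder_add(b, prop_iri, RDF_TYPE, OWL_TRANSITIVE_PROPERTY),
            Inverse    = builder_add(b, prop_iri, OWL_INVERSE_OF, a$resource),
            stop("marker '", a$marker, "' is not a field-level marker",
                 call. = FALSE)
          )
        }
      }
    }
  }
  builder_freeze(b)
}

#' Attach one property restriction to a class
#'
#' Builds the anonymous `owl:Restriction` for a single value or cardinality
#' marker and wires it as an `rdfs:subClassOf` of the class.  This is the
#' primitive [apply_semantics()] uses for every restriction marker; exposed
#' for callers constructing graphs piecemeal.
#'
#' @param graph Graph holding the class and property.
#' @param class_name Simple name of the constrained class.
#' @param field_name Name of the constrained field.
#' @param annotation A [semantic_annotation()] whose marker is one of
#'   `AllValuesFrom`, `SomeValuesFrom`, `Cardinality`, `MinCardinality`,
#'   `MaxCardinality`.
#' @param cfg A [mapping_config()].
#' @return The enlarged `ontology_graph`.
#' @export
build_restriction <- function(graph, class_name, field_name, annotation,
                              cfg = mapping_config()) {
  if (!(annotation$marker %in% restriction_markers())) {
    stop("marker '", annotation$marker, "' does not build a restriction; ",
         "expected one of: ", paste(restriction_markers(), collapse = ", "))
  }
  b <- graph_builder(graph)
  sigs <- new.env(parent = emptyenv())
  sigs$seen <- existing_restriction_sigs(graph$triples)
  build_restriction_on(b, graph$triples, sigs,
                       mint_iri("class", class_name, cfg),
                       mint_iri("property", field_name, cfg),
                       annotation, cfg)
  builder_freeze(b)
}

#' One-call mapping pipeline
#'
#' Structure, then instances (if any), then semantic annotations.
#'
#' @param classes List of [class_model()] objects.
#' @param instances Optional list of [instance_record()] objects.
#' @param cfg A [mapping_config()].
#' @return The complete `ontology_graph`.
#' @export
map_model <- function(classes, instances = list(), cfg = mapping_config()) {
  g <- map_structure(classes, cfg)
  g <- apply_semantics(g, classes, cfg)
  if (length(instances)) g <- map_instances(g, instances, cfg, classes)
  g
}
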