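# Portable intermediate representation (IR) of an annotated object model.
#
# The IR decouples the two front ends (native S4 introspection and the
# YAML/JSON model documents) from the OWL mapping engine.  Objects are plain
# S3 lists; constructors check argument *shapes* only, while model-level
# invariants are collected -- as data, not exceptions -- by validate_model().

#' Atomic field kinds
#'
#' The closed set of scalar kinds a field may carry.  Each maps to one XSD
#' datatype via [atomic_to_datatype()].
#'
#' @return Character vector of the six recognised kind tags.
#' @export
atomic_kinds <- function() {
  c("string", "integer", "decimal", "boolean", "date", "datetime")
}

#' Semantic annotation markers
#'
#' The closed set of enrichment markers the mapper understands, one per OWL
#' construct it can emit.  `level` selects the subset legal on classes
#' (`"class"`) or on fields (`"field"`).
#'
#' @param level `"all"`, `"class"` or `"field"`.
#' @return Character vector of marker names.
#' @export
annotation_markers <- function(level = c("all", "class", "field")) {
  level <- match.arg(level)
  class_level <- c("EquivalentClass", "SameAs", "DifferentFrom", "AllDifferent")
  field_level <- c("EquivalentProperty", "Symmetric", "Inverse", "AllValuesFrom",
                   "Transitive", "Cardinality", "MaxCardinality", "MinCardinality",
                   "SomeValuesFrom")
  switch(level,
    all   = c(class_level, field_level),
    class = class_level,
    field = field_level
  )
}

# Which parameter slot a marker populates.
marker_slot <- function(marker) {
  if (marker %in% c("Cardinality", "MaxCardinality", "MinCardinality")) return("number")
  if (marker %in% c("Symmetric", "Transitive")) return("none")
  if (marker == "SomeValuesFrom") return("resource_or_strings")
  "resource"
}

#' Construct a semantic annotation
#'
#' One enrichment marker with its parameter.  Cardinality markers carry a
#' non-negative integer, `Symmetric`/`Transitive` carry nothing,
#' `SomeValuesFrom` carries either a resource IRI or a list of string values
#' (rendered as an `owl:DataRange`/`owl:oneOf` list), and all remaining
#' markers carry a resource IRI.
#'
#' @param marker Marker name; see [annotation_markers()].
#' @param resource Absolute IRI, for resource-parameterised markers.
#' @param number Non-negative integer, for cardinality markers.
#' @param string_values Character vector, for the string-values form of
#'   `SomeValuesFrom`.
#' @return An object of class `owlgen_annotation`.
#' @examples
#' semantic_annotation("Cardinality", number = 1)
#' semantic_annotation("EquivalentClass", resource = "http://cz.zcu.kiv/TestedSubject")
#' @export
semantic_annotation <- function(marker, resource = NULL, number = NULL,
                                string_values = NULL) {
  stopifnot(is.character(marker), length(marker) == 1L)
  if (!is.null(resource)) stopifnot(is.character(resource), length(resource) == 1L)
  if (!is.null(number)) {
    stopifnot(is.numeric(number), length(number) == 1L)
    number <- as.integer(number)
  }
  if (!is.null(string_values)) string_values <- as.character(string_values)
  structure(
    list(marker = marker, resource = resource, number = number,
         string_values = string_values),
    class = "owlgen_annotation"
  )
}

#' Construct a field model
#'
#' One typed field of a class: an atomic scalar, a reference to another
#' modelled class, or a homogeneous collection of such references.
#'
#' @param name Field name (identifier string).
#' @param kind `"atomic"`, `"reference"` or `"collection"`.
#' @param atomic_kind Scalar kind, required iff `kind = "atomic"`;
#'   see [atomic_kinds()].
#' @param target_class Simple name of the referenced class, required iff
#'   `kind` is `"reference"` or `"collection"`.
#' @param is_identifier Whether this field carries the instance identifier
#'   used for individual IRI minting.
#' @param annotations List of [semantic_annotation()] objects.
#' @return An object of class `owlgen_field`.
#' @export
field_model <- function(name, kind, atomic_kind = NULL, target_class = NULL,
                        is_identifier = FALSE, annotations = list()) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(kind), length(kind) == 1L,
            is.logical(is_identifier), length(is_identifier) == 1L,
            is.list(annotations))
  structure(
    list(name = name, kind = kind, atomic_kind = atomic_kind,
         target_class = target_class, is_identifier = is_identifier,
         annotations = annotations),
    class = "owlgen_field"
  )
}

#' Construct a class model
#'
#' One source class: its simple and dotted qualified names, optional single
#' superclass, fields, class-level annotations, and -- for enumerations --
#' the literal set.
#'
#' @param simple_name Simple class name (used for IRI minting).
#' @param qualified_name Dotted source name (package + class); recorded on the
#'   emitted `owl:Class` through the source-class annotation property.
#' @param superclass Simple name of the superclass, or `NULL`.
#' @param is_enumeration Whether the class is an enumeration.
#' @param enum_literals Character vector of literals (enumerations only).
#' @param fields List of [field_model()] objects, in declaration order.
#' @param annotations Class-level [semantic_annotation()] list.
#' @return An object of class `owlgen_class`.
#' @examples
#' class_model("Person", "cz.zcu.kiv.Person", fields = list(
#'   field_model("id", "atomic", atomic_kind = "integer", is_identifier = TRUE),
#'   field_model("firstname", "atomic", atomic_kind = "string"),
#'   field_model("researchGroups", "collection", target_class = "ResearchGroup")
#' ))
#' @export
class_model <- function(simple_name, qualified_name = simple_name,
                        superclass = NULL, is_enumeration = FALSE,
                        enum_literals = character(), fields = list(),
                        annotations = list()) {
  stopifnot(is.character(simple_name), length(simple_name) == 1L,
            is.character(qualified_name), length(qualified_name) == 1L,
            is.logical(is_enumeration), length(is_enumeration) == 1L,
            is.list(fields), is.list(annotations))
  if (!is.null(superclass)) stopifnot(is.character(superclass), length(superclass) == 1L)
  structure(
    list(simple_name = simple_name, qualified_name = qualified_name,
         superclass = superclass, is_enumeration = is_enumeration,
         enum_literals = as.character(enum_literals), fields = fields,
         annotations = annotations),
    class = "owlgen_class"
  )
}

#' Construct an instance record
#'
#' One source object: its class, a local identifier, and field values.
#' Reference-valued entries hold the local id of the referenced record
#' (a vector/list of ids for collections); enumeration-valued entries hold
#' one of the enumeration's literals.
#'
#' @param class_name Simple name of the record's class.
#' @param local_id Identifier, unique within the class (string or integer).
#' @param values Named list, field name -> value.
#' @return An object of class `owlgen_instance`.
#' @export
instance_record <- function(class_name, local_id, values = list()) {
  stopifnot(is.character(class_name), length(class_name) == 1L,
            length(local_id) == 1L, is.list(values))
  structure(
    list(class_name = class_name, local_id = as.character(local_id),
         values = values),
    class = "owlgen_instance"
  )
}

#' @export
print.owlgen_class <- function(x, ...) {
  kind <- if (isTRUE(x$is_enumeration)) "enumeration" else "class"
  cat(sprintf("<owlgen %s> %s (%s)\n", kind, x$simple_name, x$qualified_name))
  if (!is.null(x$superclass)) cat("  extends:", x$superclass, "\n")
  if (isTRUE(x$is_enumeration)) {
    cat("  literals:", paste(x$enum_literals, collapse = ", "), "\n")
  }
  for (f in x$fields) {
    tgt <- if (f$kind == "atomic") f$atomic_kind else f$target_class
    cat(sprintf("  %s: %s<%s>%s\n", f$name, f$kind, tgt %||% "?",
                if (isTRUE(f$is_identifier)) " [id]" else ""))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- model indexing helpers ------------------------------------------------

model_index <- function(classes) {
  nm <- vapply(classes, function(cl) cl$simple_name, character(1))
  stats::setNames(classes, nm)
}

# Fields visible on a class: own plus inherited, superclass-first.
effective_fields <- function(class_name, index) {
  out <- list()
  seen <- character()
  nm <- class_name
  while (!is.null(nm) && nm %in% names(index) && !(nm %in% seen)) {
    seen <- c(seen, nm)
    out <- c(index[[nm]]$fields, out)
    nm <- index[[nm]]$superclass
  }
  out
}

# ---- validation ------------------------------------------------------------

new_violation <- function(message, class = NA_character_, field = NA_character_,
                          instance = NA_character_) {
  data.frame(class = class, field = field, instance = instance,
             message = message, stringsAsFactors = FALSE)
}

empty_report <- function() {
  data.frame(class = character(), field = character(), instance = character(),
             message = character(), stringsAsFactors = FALSE)
}

check_annotation <- function(a, level, cls, fld = NA_character_) {
  v <- empty_report()
  if (!inherits(a, "owlgen_annotation")) {
    return(new_violation("annotation is not an owlgen_annotation object", cls, fld))
  }
  if (!(a$marker %in% annotation_markers())) {
    return(new_violation(sprintf("unknown annotation marker '%s'", a$marker), cls, fld))
  }
  if (!(a$marker %in% annotation_markers(level))) {
    v <- rbind(v, new_violation(
      sprintf("marker '%s' is not allowed at %s level", a$marker, level), cls, fld))
  }
  slot <- marker_slot(a$marker)
  has_res <- !is.null(a$resource)
  has_num <- !is.null(a$number)
  has_str <- !is.null(a$string_values) && length(a$string_values) > 0L
  ok <- switch(slot,
    number = has_num && !has_res && !has_str,
    none = !has_num && !has_res && !has_str,
    resource_or_strings = xor(has_res, has_str) && !has_num,
    resource = has_res && !has_num && !has_str
  )
  if (!ok) {
    v <- rbind(v, new_violation(
      sprintf("marker '%s' has the wrong parameter slot populated (expects %s)",
              a$marker, slot), cls, fld))
  }
  if (has_num && a$number < 0L) {
    v <- rbind(v, new_violation(
      sprintf("marker '%s' carries a negative cardinality", a$marker), cls, fld))
  }
  v
}

check_field <- function(f, cls, index) {
  v <- empty_report()
  if (!inherits(f, "owlgen_field")) {
    return(new_violation("field is not an owlgen_field object", cls))
  }
  nm <- f$name
  if (!(f$kind %in% c("atomic", "reference", "collection"))) {
    v <- rbind(v, new_violation(sprintf("unknown field kind '%s'", f$kind), cls, nm))
    return(v)
  }
  if (f$kind == "atomic") {
    if (is.null(f$atomic_kind) || !is.null(f$target_class)) {
      v <- rbind(v, new_violation(
        "atomic field must populate atomic_kind and not target_class", cls, nm))
    } else if (!(f$atomic_kind %in% atomic_kinds())) {
      v <- rbind(v, new_violation(
        sprintf("unknown atomic kind '%s'", f$atomic_kind), cls, nm))
    }
  } else {
    if (is.null(f$target_class) || !is.null(f$atomic_kind)) {
      v <- rbind(v, new_violation(sprintf(
        "%s field must populate target_class and not atomic_kind", f$kind), cls, nm))
    } else if (!(f$target_class %in% names(index))) {
      v <- rbind(v, new_violation(sprintf(
        "target class '%s' is not defined in the model", f$target_class), cls, nm))
    }
  }
  for (a in f$annotations) {
    v <- rbind(v, check_annotation(a, "field", cls, nm))
    if (inherits(a, "owlgen_annotation") &&
        a$marker %in% c("Symmetric", "Transitive", "Inverse") &&
        identical(f$kind, "atomic")) {
      v <- rbind(v, new_violation(sprintf(
        "marker '%s' requires an object property; field is atomic", a$marker), cls, nm))
    }
  }
  v
}

# Ranges of all same-named fields must agree: OWL properties are global.
check_global_properties <- function(classes, index) {
  v <- empty_report()
  sig <- function(f) {
    if (f$kind == "atomic") paste0("datatype:", f$atomic_kind)
    else paste0("object:", f$target_class)
  }
  seen <- list()
  for (cl in classes) {
    if (!inherits(cl, "owlgen_class")) next
    for (f in cl$fields) {
      if (!inherits(f, "owlgen_field")) next
      s <- tryCatch(sig(f), error = function(e) NA_character_)
      if (is.na(s) || is.null(f$name)) next
      prev <- seen[[f$name]]
      if (is.null(prev)) {
        seen[[f$name]] <- list(sig = s, class = cl$simple_name)
      } else if (!identical(prev$sig, s)) {
        v <- rbind(v, new_violation(sprintf(
          "field '%s' declared with conflicting ranges in classes '%s' and '%s'",
          f$name, prev$class, cl$simple_name), cl$simple_name, f$name))
      }
    }
  }
  v
}

check_instance <- function(inst, index, id_index) {
  v <- empty_report()
  tag <- paste0(inst$class_name, "#", inst$local_id)
  if (!(inst$class_name %in% names(index))) {
    return(new_violation(sprintf("instance names unknown class '%s'", inst$class_name),
                         instance = tag))
  }
  cl <- index[[inst$class_name]]
  if (isTRUE(cl$is_enumeration)) {
    return(new_violation("instances of enumeration classes are not allowed",
                         cl$simple_name, instance = tag))
  }
  fields <- effective_fields(inst$class_name, index)
  fmap <- stats::setNames(fields, vapply(fields, `[[`, character(1), "name"))
  for (nm in names(inst$values)) {
    val <- inst$values[[nm]]
    if (!(nm %in% names(fmap))) {
      v <- rbind(v, new_violation(sprintf("value for unknown field '%s'", nm),
                                  cl$simple_name, nm, tag))
      next
    }
    f <- fmap[[nm]]
    if (f$kind == "atomic") {
      if (!atomic_value_ok(val, f$atomic_kind)) {
        v <- rbind(v, new_violation(sprintf(
          "value for atomic field '%s' does not match kind '%s'", nm, f$atomic_kind),
          cl$simple_name, nm, tag))
      }
    } else {
      ids <- unlist(val, use.names = FALSE)
      if (f$kind == "reference" && length(ids) != 1L) {
        v <- rbind(v, new_violation(sprintf(
          "reference field '%s' must hold exactly one id", nm), cl$simple_name, nm, tag))
        next
      }
      target <- index[[f$target_class]]
      if (is.null(target)) next  # reported by the structural checks
      if (isTRUE(target$is_enumeration)) {
        bad <- setdiff(as.character(ids), target$enum_literals)
        if (length(bad)) {
          v <- rbind(v, new_violation(sprintf(
            "value '%s' is not a literal of enumeration '%s'", bad[[1L]],
            target$simple_name), cl$simple_name, nm, tag))
        }
      } else {
        for (id in as.character(ids)) {
          ref_cls <- id_index[[id]]
          if (is.null(ref_cls)) {
            v <- rbind(v, new_violation(sprintf(
              "field '%s' references unknown instance id '%s'", nm, id),
              cl$simple_name, nm, tag))
          } else if (!class_is_a(ref_cls, f$target_class, index)) {
            v <- rbind(v, new_violation(sprintf(
              "field '%s' references instance '%s' of class '%s', expected '%s'",
              nm, id, ref_cls, f$target_class), cl$simple_name, nm, tag))
          }
        }
      }
    }
  }
  v
}

atomic_value_ok <- function(val, kind) {
  if (length(val) != 1L) return(FALSE)
  val <- val[[1L]]
  switch(kind,
    string   = is.character(val),
    integer  = (is.numeric(val) && val == as.integer(val)),
    decimal  = is.numeric(val),
    boolean  = is.logical(val),
    date     = inherits(val, "Date") ||
               (is.character(val) && grepl("^\\d{4}-\\d{2}-\\d{2}$", val)),
    datetime = inherits(val, "POSIXt") ||
               (is.character(val) &&
                grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}", val)),
    FALSE
  )
}

# Is `cls` equal to, or a (transitive) subclass of, `target`?
class_is_a <- function(cls, target, index) {
  seen <- character()
  while (!is.null(cls) && !(cls %in% seen)) {
    if (identical(cls, target)) return(TRUE)
    seen <- c(seen, cls)
    cls <- if (cls %in% names(index)) index[[cls]]$superclass else NULL
  }
  FALSE
}

#' Validate an object model and optional instances
#'
#' Collects every invariant violation -- unknown kinds and markers, misfiled
#' annotation parameters, unresolved or conflicting references, inheritance
#' cycles, duplicate names, ill-shaped instance values -- as rows of a report.
#' An empty report means the model is accepted by every downstream operation.
#'
#' @param classes List of [class_model()] objects.
#' @param instances Optional list of [instance_record()] objects.
#' @return A data frame with columns `class`, `field`, `instance`, `message`;
#'   zero rows iff the model (and instances) are valid.
#' @examples
#' m <- list(class_model("A", fields = list(
#'   field_model("x", "atomic", atomic_kind = "string"))))
#' nrow(validate_model(m)) == 0
#' @export
validate_model <- function(classes, instances = list()) {
  v <- empty_report()
  if (!is.list(classes)) stop("`classes` must be a list of class models")
  nms <- vapply(classes, function(cl) {
    if (inherits(cl, "owlgen_class")) cl$simple_name else NA_character_
  }, character(1))
  if (anyNA(nms)) {
    v <- rbind(v, new_violation("model entries must be owlgen_class objects"))
  }
  dup <- unique(nms[duplicated(nms) & !is.na(nms)])
  for (d in dup) {
    v <- rbind(v, new_violation(sprintf("duplicate class simple name '%s'", d), d))
  }
  index <- model_index(classes[!is.na(nms)])

  for (cl in classes) {
    if (!inherits(cl, "owlgen_class")) next
    cn <- cl$simple_name
    fn <- vapply(cl$fields, function(f) f$name %||% NA_character_, character(1))
    for (d in unique(fn[duplicated(fn)])) {
      v <- rbind(v, new_violation(sprintf("duplicate field name '%s'", d), cn, d))
    }
    n_id <- sum(vapply(cl$fields, function(f) isTRUE(f$is_identifier), logical(1)))
    if (n_id > 1L) {
      v <- rbind(v, new_violation("more than one identifier field", cn))
    }
    if (!is.null(cl$superclass)) {
      if (!(cl$superclass %in% names(index))) {
        v <- rbind(v, new_violation(sprintf(
          "superclass '%s' is not defined in the model", cl$superclass), cn))
      } else {
        # walk up; a cycle returns to cn
        seen <- cn; p <- cl$superclass
        while (!is.null(p) && p %in% names(index)) {
          if (p %in% seen) {
            v <- rbind(v, new_violation("inheritance cycle detected", cn))
            break
          }
          seen <- c(seen, p)
          p <- index[[p]]$superclass
        }
      }
    }
    if (isTRUE(cl$is_enumeration)) {
      if (length(cl$enum_literals) == 0L) {
        v <- rbind(v, new_violation("enumeration with no literals", cn))
      }
      if (anyDuplicated(cl$enum_literals)) {
        v <- rbind(v, new_violation("duplicate enumeration literals", cn))
      }
      if (length(cl$fields) > 0L) {
        v <- rbind(v, new_violation("enumeration classes cannot declare fields", cn))
      }
    }
    for (a in cl$annotations) v <- rbind(v, check_annotation(a, "class", cn))
    for (f in cl$fields) v <- rbind(v, check_field(f, cn, index))
  }

  v <- rbind(v, check_global_properties(classes, index))

  if (length(instances)) {
    ids <- vapply(instances, function(i) i$local_id, character(1))
    cls <- vapply(instances, function(i) i$class_name, character(1))
    for (d in unique(ids[duplicated(ids)])) {
      v <- rbind(v, new_violation(sprintf("duplicate instance id '%s'", d),
                                  instance = d))
    }
    id_index <- stats::setNames(as.list(cls), ids)
    for (inst in instances) {
      v <- rbind(v, check_instance(inst, index, id_index))
    }
  }
  rownames(v) <- NULL
  v
}
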