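# Native front end: produces the IR from S4 class declarations.
#
# S4 is R's standard typed-field idiom: slots are declared with their class,
# single inheritance via `contains`.  What S4 lacks natively -- semantic
# markers, enumerations, element-typed collections -- is attached through a
# small model registry, the analogue of run-time-readable annotations:
#
#   setClass("ResearchGroup", representation(title = "character"))
#   setClass("Person", representation(id = "integer", firstname = "character",
#                                     researchGroups = list_of("ResearchGroup")))
#   annotate_model("Person", package = "cz.zcu.kiv", identifier = "id",
#     fields = list(firstname = list(semantic_annotation("SomeValuesFrom",
#       string_values = "http://cz.zcu.kiv/GivenNames"))))
#   scan_native_model(c("Person", "ResearchGroup"))

.owlgen_registry <- new.env(parent = emptyenv())

registry_get <- function(kind, key) {
  tab <- .owlgen_registry[[kind]]
  if (is.null(tab)) NULL else tab[[key]]
}

registry_set <- function(kind, key, value) {
  tab <- .owlgen_registry[[kind]] %||% list()
  tab[[key]] <- value
  .owlgen_registry[[kind]] <- tab
  invisible(value)
}

#' Reset the native model registry
#'
#' Clears every [list_of()], [enum_class()] and [annotate_model()]
#' registration.  Mainly useful between independent model definitions in one
#' session.
#'
#' @return Invisibly `NULL`.
#' @export
reset_model_registry <- function() {
  rm(list = ls(.owlgen_registry), envir = .owlgen_registry)
  invisible(NULL)
}

#' Declare a collection slot type
#'
#' Defines (once) an S4 class `<element>List` containing `list` and records
#' its element type, so a slot declared with the returned class name scans as
#' a collection field of that element class.
#'
#' @param element Simple name of the element class.
#' @param where Environment in which to define the list class.
#' @return The generated class name, for use in `representation()`.
#' @export
list_of <- function(element, where = topenv(parent.frame())) {
  stopifnot(is.character(element), length(element) == 1L)
  nm <- paste0(element, "List")
  if (!methods::isClass(nm, where = where)) {
    methods::setClass(nm, contains = "list", where = where)
  }
  registry_set("collections", nm, element)
  nm
}

#' Declare an enumeration
#'
#' Registers a closed literal set under a class name (and defines a nominal
#' S4 class so slots may be typed with it).  Scanned as an enumeration
#' ClassModel, mapped to an `owl:oneOf` class.
#'
#' @param name Enumeration class name.
#' @param literals Character vector of literals.
#' @param package Optional dotted package prefix for the qualified name.
#' @param where Environment in which to define the nominal class.
#' @return `name`, invisibly.
#' @export
enum_class <- function(name, literals, package = NULL,
                       where = topenv(parent.frame())) {
  stopifnot(is.character(name), length(name) == 1L, length(literals) >= 1L)
  if (!methods::isClass(name, where = where)) {
    methods::setClass(name, representation(.value = "character"), where = where)
  }
  registry_set("enums", name, list(literals = as.character(literals),
                                   package = package))
  invisible(name)
}

#' Attach semantic markers to a native class
#'
#' The run-time metadata channel of the native front end: class-level
#' markers, per-field markers, the identifier field, and the dotted package
#' prefix used for the qualified source name.
#'
#' @param class_name Name of the S4 class.
#' @param annotations List of class-level [semantic_annotation()] objects.
#' @param fields Named list: field name -> list of [semantic_annotation()]s.
#' @param identifier Name of the identifier field, or `NULL`.
#' @param package Dotted package prefix (qualified name becomes
#'   `package.ClassName`).
#' @return `class_name`, invisibly.
#' @export
annotate_model <- function(class_name, annotations = list(), fields = list(),
                           identifier = NULL, package = NULL) {
  stopifnot(is.character(class_name), length(class_name) == 1L)
  registry_set("annotations", class_name,
               list(annotations = annotations, fields = fields,
                    identifier = identifier, package = package))
  invisible(class_name)
}

atomic_slot_map <- c(character = "string", integer = "integer",
                     numeric = "decimal", logical = "boolean",
                     Date = "date", POSIXct = "datetime")

#' Scan native S4 classes into the IR
#'
#' One ClassModel per class: slot types resolve to atomic kinds (`character`,
#' `integer`, `numeric`, `logical`, `Date`, `POSIXct`), to references (a slot
#' typed by another scanned class or [enum_class()]), or to collections (a
#' slot typed by a [list_of()] class).  `contains =` becomes the superclass;
#' registry markers become the class's annotations.  Unresolvable slot types
#' or markers naming unknown fields fail the scan with the class and field
#' named.
#'
#' @param class_names Character vector of S4 class names, in model order.
#' @param where Environment in which the classes are defined.
#' @return List of [class_model()] objects.
#' @export
scan_native_model <- function(class_names, where = topenv(parent.frame())) {
  class_names <- as.character(class_names)
  lapply(class_names, function(nm) scan_one_class(nm, class_names, where))
}

scan_one_class <- function(nm, model_names, where) {
  meta <- registry_get("annotations", nm) %||% list()
  qualified <- if (!is.null(meta$package)) paste0(meta$package, ".", nm) else nm

  enum <- registry_get("enums", nm)
  if (!is.null(enum)) {
    if (!is.null(enum$package)) qualified <- paste0(enum$package, ".", nm)
    return(class_model(nm, qualified, is_enumeration = TRUE,
                       enum_literals = enum$literals,
                       annotations = meta$annotations %||% list()))
  }

  cdef <- tryCatch(methods::getClass(nm, where = where),
                   error = function(e) NULL)
  if (is.null(cdef)) {
    stop("cannot scan class '", nm, "': no S4 definition found", call. = FALSE)
  }

  contains <- cdef@contains
  direct <- names(contains)[vapply(contains, function(x) x@distance == 1L,
                                   logical(1))]
  superclass <- NULL
  parent_slots <- character()
  if (length(direct)) {
    direct <- direct[[1L]]
    if (direct %in% model_names) {
      superclass <- direct
      parent_slots <- names(methods::getClass(direct, where = where)@slots)
    } else if (!(direct %in% c("list", ".environment"))) {
      stop("cannot scan class '", nm, "': superclass '", direct,
           "' is not part of the scanned model", call. = FALSE)
    }
  }

  slots <- cdef@slots
  own <- setdiff(names(slots), parent_slots)
  fields <- lapply(own, function(fname) {
    ftype <- as.character(slots[[fname]])
    fann <- (meta$fields %||% list())[[fname]] %||% list()
    is_id <- identical(meta$identifier, fname)
    if (ftype %in% names(atomic_slot_map)) {
      field_model(fname, "atomic", atomic_kind = atomic_slot_map[[ftype]],
                  is_identifier = is_id, annotations = fann)
    } else if (!is.null(el <- registry_get("collections", ftype))) {
      field_model(fname, "collection", target_class = el,
                  is_identifier = is_id, annotations = fann)
    } else if (ftype %in% model_names) {
      field_model(fname, "reference", target_class = ftype,
                  is_identifier = is_id, annotations = fann)
    } else {
      stop("cannot scan class '", nm, "': field '", fname,
           "' has unresolved type '", ftype, "'", call. = FALSE)
    }
  })

  for (marked in names(meta$fields %||% list())) {
    if (!(marked %in% own)) {
      stop("cannot scan class '", nm, "': marker attached to unknown field '",
           marked, "'", call. = FALSE)
    }
  }
  if (!is.null(meta$identifier) && !(meta$identifier %in% own)) {
    stop("cannot scan class '", nm, "': identifier names unknown field '",
         meta$identifier, "'", call. = FALSE)
  }

  class_model(nm, qualified, superclass = superclass, fields = fields,
              annotations = meta$annotations %||% list())
}

# Render an IR model as native S4 declarations (the inverse of
# scan_native_model); used by the round-trip property tests.
render_native_model <- function(classes, where) {
  inv_atomic <- stats::setNames(names(atomic_slot_map), atomic_slot_map)
  # supers first, so subclass definitions see the full parent slot set
  nms <- vapply(classes, `[[`, character(1), "simple_name")
  ordered <- list(); done <- character()
  pending <- classes
  while (length(pending)) {
    ready <- vapply(pending, function(cl) {
      is.null(cl$superclass) || !(cl$superclass %in% nms) ||
        cl$superclass %in% done
    }, logical(1))
    if (!any(ready)) stop("inheritance cycle in model", call. = FALSE)
    ordered <- c(ordered, pending[ready])
    done <- c(done, vapply(pending[ready], `[[`, character(1), "simple_name"))
    pending <- pending[!ready]
  }
  for (cl in ordered) {
    pkg <- sub(paste0("\\.?", cl$simple_name, "$"), "", cl$qualified_name)
    if (!nzchar(pkg)) pkg <- NULL
    if (isTRUE(cl$is_enumeration)) {
      enum_class(cl$simple_name, cl$enum_literals, package = pkg, where = where)
      if (length(cl$annotations)) {
        annotate_model(cl$simple_name, annotations = cl$annotations,
                       package = pkg)
      }
      next
    }
    rep_args <- list()
    for (f in cl$fields) {
      rep_args[[f$name]] <- switch(f$kind,
        atomic = inv_atomic[[f$atomic_kind]],
        reference = f$target_class,
        collection = list_of(f$target_class, where = where)
      )
    }
    # referenced classes may not be defined yet; register placeholders
    for (tp in unlist(rep_args, use.names = FALSE)) {
      if (!(tp %in% names(atomic_slot_map)) && !methods::isClass(tp, where = where)) {
        methods::setClass(tp, representation(), where = where)
      }
    }
    args <- list(Class = cl$simple_name,
                 representation = do.call(methods::representation, rep_args),
                 where = where)
    if (!is.null(cl$superclass)) {
      if (!methods::isClass(cl$superclass, where = where)) {
        methods::setClass(cl$superclass, representation(), where = where)
      }
      args$contains <- cl$superclass
    }
    do.call(methods::setClass, args)
    idf <- NULL
    fanns <- list()
    for (f in cl$fields) {
      if (isTRUE(f$is_identifier)) idf <- f$name
      if (length(f$annotations)) fanns[[f$name]] <- f$annotations
    }
    if (!is.null(idf) || length(fanns) || length(cl$annotations) || !is.null(pkg)) {
      annotate_model(cl$simple_name, annotations = cl$annotations,
                     fields = fanns, identifier = idf, package = pkg)
    }
  }
  invisible(where)
}
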