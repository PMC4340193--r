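# Portable model-description documents (YAML/JSON) and instance documents
# (JSON): the cross-language front end that yields the same IR as native
# introspection.  The shipped JSON Schemas (inst/schemas/) describe the
# formats; the checks below enforce them, reporting the document path of the
# first offending element.

schema_error <- function(path, msg) {
  stop(structure(
    class = c("owlgen_schema_error", "error", "condition"),
    list(message = sprintf("schema violation at %s: %s", path, msg),
         call = NULL)
  ))
}

check_keys <- function(x, allowed, required, path) {
  if (!is.list(x)) schema_error(path, "expected a mapping")
  nm <- names(x)
  if (length(x) && (is.null(nm) || any(!nzchar(nm)))) {
    schema_error(path, "expected a mapping with named keys")
  }
  extra <- setdiff(nm, allowed)
  if (length(extra)) schema_error(path, paste0("unknown key '", extra[[1L]], "'"))
  missing <- setdiff(required, nm)
  if (length(missing)) schema_error(path, paste0("missing key '", missing[[1L]], "'"))
}

scalar_chr <- function(x, path, what = "a string") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    schema_error(path, paste0("expected ", what))
  }
  x
}

doc_annotation <- function(a, path) {
  check_keys(a, c("marker", "resource", "number", "string_values"),
             "marker", path)
  marker <- scalar_chr(a$marker, paste0(path, ".marker"))
  if (!(marker %in% annotation_markers())) {
    schema_error(paste0(path, ".marker"), paste0("unknown marker '", marker, "'"))
  }
  if (!is.null(a$number) && (!is.numeric(a$number) || length(a$number) != 1L)) {
    schema_error(paste0(path, ".number"), "expected an integer")
  }
  sv <- a$string_values
  if (!is.null(sv)) {
    sv <- unlist(sv, use.names = FALSE)
    if (!is.character(sv)) {
      schema_error(paste0(path, ".string_values"), "expected a list of strings")
    }
  }
  semantic_annotation(marker,
                      resource = if (is.null(a$resource)) NULL
                                 else scalar_chr(a$resource, paste0(path, ".resource")),
                      number = a$number,
                      string_values = sv)
}

doc_field <- function(f, path) {
  check_keys(f, c("name", "type", "collection", "id", "annotations"),
             c("name", "type"), path)
  name <- scalar_chr(f$name, paste0(path, ".name"))
  type <- scalar_chr(f$type, paste0(path, ".type"))
  collection <- isTRUE(f$collection)
  is_id <- isTRUE(f$id)
  anns <- lapply(seq_along(f$annotations %||% list()), function(i) {
    doc_annotation(f$annotations[[i]], paste0(path, ".annotations[", i, "]"))
  })
  if (collection) {
    field_model(name, "collection", target_class = type,
                is_identifier = is_id, annotations = anns)
  } else if (type %in% atomic_kinds()) {
    field_model(name, "atomic", atomic_kind = type,
                is_identifier = is_id, annotations = anns)
  } else {
    field_model(name, "reference", target_class = type,
                is_identifier = is_id, annotations = anns)
  }
}

doc_class <- function(cl, path) {
  check_keys(cl, c("name", "package", "extends", "enum", "fields", "annotations"),
             "name", path)
  name <- scalar_chr(cl$name, paste0(path, ".name"))
  qualified <- if (!is.null(cl$package)) {
    paste0(scalar_chr(cl$package, paste0(path, ".package")), ".", name)
  } else name
  literals <- unlist(cl$enum %||% list(), use.names = FALSE)
  fields <- lapply(seq_along(cl$fields %||% list()), function(i) {
    doc_field(cl$fields[[i]], paste0(path, ".fields[", i, "]"))
  })
  anns <- lapply(seq_along(cl$annotations %||% list()), function(i) {
    doc_annotation(cl$annotations[[i]], paste0(path, ".annotations[", i, "]"))
  })
  class_model(name, qualified,
              superclass = if (is.null(cl$extends)) NULL
                           else scalar_chr(cl$extends, paste0(path, ".extends")),
              is_enumeration = !is.null(cl$enum),
              enum_literals = as.character(literals),
              fields = fields, annotations = anns)
}

#' Parse a model-description document
#'
#' Reads the portable YAML/JSON description of an object model into the same
#' IR that [scan_native_model()] produces for the equivalent native class
#' declarations.
#'
#' @param text Document text, or a file path to read.
#' @param format `"yaml"` or `"json"`.
#' @return List of [class_model()] objects.
#' @examples
#' doc <- "
#' classes:
#'   - name: Person
#'     package: cz.zcu.kiv
#'     fields:
#'       - {name: firstname, type: string}
#' "
#' parse_model_document(doc, "yaml")
#' @export
parse_model_document <- function(text, format = c("yaml", "json")) {
  format <- match.arg(format)
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE, encoding = "UTF-8"),
                  collapse = "\n")
  } else {
    text <- paste(text, collapse = "\n")
  }
  data <- if (format == "yaml") {
    yaml::yaml.load(text)
  } else {
    jsonlite::fromJSON(text, simplifyVector = FALSE)
  }
  if (is.null(data)) data <- list()
  check_keys(data, "classes", "classes", "$")
  if (!is.list(data$classes)) schema_error("$.classes", "expected a list")
  lapply(seq_along(data$classes), function(i) {
    doc_class(data$classes[[i]], paste0("$.classes[", i, "]"))
  })
}

#' Write a model as a portable document
#'
#' Inverse of [parse_model_document()]: renders the IR as YAML or JSON text
#' that parses back to an identical model.
#'
#' @param classes List of [class_model()] objects.
#' @param format `"yaml"` or `"json"`.
#' @return Document text.
#' @export
write_model_document <- function(classes, format = c("yaml", "json")) {
  format <- match.arg(format)
  ann_doc <- function(a) {
    out <- list(marker = a$marker)
    if (!is.null(a$resource)) out$resource <- a$resource
    if (!is.null(a$number)) out$number <- a$number
    if (!is.null(a$string_values)) out$string_values <- as.list(a$string_values)
    out
  }
  cls_doc <- function(cl) {
    out <- list(name = cl$simple_name)
    pkg <- sub(paste0("\\.", cl$simple_name, "$"), "", cl$qualified_name)
    if (pkg != cl$qualified_name) out$package <- pkg
    if (!is.null(cl$superclass)) out$extends <- cl$superclass
    if (isTRUE(cl$is_enumeration)) out$enum <- as.list(cl$enum_literals)
    if (length(cl$fields)) {
      out$fields <- lapply(cl$fields, function(f) {
        fd <- list(name = f$name,
                   type = if (f$kind == "atomic") f$atomic_kind else f$target_class)
        if (f$kind == "collection") fd$collection <- TRUE
        if (isTRUE(f$is_identifier)) fd$id <- TRUE
        if (length(f$annotations)) fd$annotations <- lapply(f$annotations, ann_doc)
        fd
      })
    }
    if (length(cl$annotations)) out$annotations <- lapply(cl$annotations, ann_doc)
    out
  }
  doc <- list(classes = lapply(classes, cls_doc))
  if (format == "yaml") {
    yaml::as.yaml(doc)
  } else {
    as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE))
  }
}

#' Load instance records from a JSON document
#'
#' Reads a JSON array of `{class, id, values}` objects and validates every
#' record against the model: unknown classes, dangling references and value
#' shape mismatches are reported per record.
#'
#' @param text JSON text or a file path.
#' @param model List of [class_model()] objects (must itself validate).
#' @return List of [instance_record()] objects.
#' @export
load_instances <- function(text, model) {
  stop_if_invalid(model)
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE, encoding = "UTF-8"),
                  collapse = "\n")
  } else {
    text <- paste(text, collapse = "\n")
  }
  data <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  if (!is.list(data)) schema_error("$", "expected a list of instance records")
  records <- lapply(seq_along(data), function(i) {
    rec <- data[[i]]
    path <- paste0("$[", i, "]")
    check_keys(rec, c("class", "id", "values"), c("class", "id"), path)
    vals <- rec$values %||% list()
    if (!is.list(vals)) schema_error(paste0(path, ".values"), "expected a mapping")
    vals <- lapply(vals, function(v) if (is.list(v)) unlist(v, use.names = FALSE) else v)
    instance_record(scalar_chr(rec$class, paste0(path, ".class")),
                    rec$id, values = vals)
  })
  rep <- validate_model(model, records)
  rep <- rep[!is.na(rep$instance), , drop = FALSE]
  if (nrow(rep)) {
    stop("invalid instance document (", nrow(rep), " violation",
         if (nrow(rep) > 1L) "s" else "", "): ",
         paste(utils::head(sprintf("[%s] %s", rep$instance, rep$message), 5L),
               collapse = "; "), call. = FALSE)
  }
  records
}

#' Write instance records as a JSON document
#'
#' @param instances List of [instance_record()] objects.
#' @return JSON text that [load_instances()] reads back.
#' @export
write_instance_document <- function(instances) {
  doc <- lapply(instances, function(r) {
    list(class = r$class_name, id = r$local_id,
         values = lapply(r$values, function(v) {
           if (length(v) > 1L) as.list(v) else v
         }))
  })
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE))
}
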