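#' Serialize emitted resources to disk
#'
#' JSON output is newline-delimited (one resource per line, one
#' `<domain>.ndjson` file per domain), or a single collection `Bundle` when
#' `bundle = TRUE`; XML output is one FHIR-XML file per resource. A
#' `manifest.json` with per-type counts, per-domain skip tallies and
#' crosswalk-miss tallies is always written. Output is deterministic:
#' serializing the same input twice gives byte-identical files.
#'
#' @param resource_sets Named list of resource lists, one per domain (as
#'   produced by [emit_domain()]); names become the output file names.
#' @param out_dir Output directory (created if needed).
#' @param format `"json"` or `"xml"`.
#' @param bundle Wrap all JSON output in one collection Bundle
#'   (`bundle.json`) instead of per-domain NDJSON.
#' @param crosswalk_misses Optional tibble from [crosswalk_misses()] to
#'   record in the manifest.
#' @param view_skips Optional tibble of per-domain view skip tallies.
#' @return The manifest, invisibly (class `fhir_manifest`).
#' @export
serialize_resources <- function(resource_sets, out_dir,
                                format = c("json", "xml"), bundle = FALSE,
                                crosswalk_misses = NULL, view_skips = NULL) {
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  files <- character()
  for (nm in names(resource_sets)) {
    res <- resource_sets[[nm]]
    type <- if (length(res)) res[[1]]$resourceType else NA_character_
    if (!is.na(type)) {
      counts[[type]] <- (counts[[type]] %||% 0L) + length(res)
    }
    if (format == "json" && !bundle) {
      path <- file.path(out_dir, paste0(nm, ".ndjson"))
      lines <- vapply(res, function(r) {
        as.character(jsonlite::toJSON(unclass(r), auto_unbox = TRUE,
                                      digits = NA))
      }, character(1))
      writeLines(lines, path)
      files <- c(files, basename(path))
    } else if (format == "xml") {
      for (r in res) {
        path <- file.path(out_dir, paste0(nm, "-", r$id, ".xml"))
        write_fhir_xml(r, path)
        files <- c(files, basename(path))
      }
    }
  }
  if (format == "json" && bundle) {
    all_res <- unlist(unname(resource_sets), recursive = FALSE)
    bundle_res <- list(
      resourceType = "Bundle", type = "collection",
      entry = map(all_res, function(r) list(resource = unclass(r)))
    )
    path <- file.path(out_dir, "bundle.json")
    writeLines(as.character(jsonlite::toJSON(bundle_res, auto_unbox = TRUE,
                                             digits = NA)), path)
    files <- c(files, basename(path))
  }
  skipped_at_emit <- map_int(resource_sets,
                             function(r) attr(r, "skipped") %||% 0L)
  manifest <- structure(list(
    resource_counts = counts,
    skipped_at_emit = as.list(skipped_at_emit),
    view_skips = if (!is.null(view_skips) && nrow(view_skips))
      as.list(split(view_skips$n,
                    paste(view_skips$domain, view_skips$reason, sep = ":")))
      else list(),
    crosswalk_misses = if (!is.null(crosswalk_misses) &&
                           nrow(crosswalk_misses))
      as.list(setNames(crosswalk_misses$misses,
                       paste(crosswalk_misses$table_cd,
                             crosswalk_misses$column_cd, sep = ".")))
      else list(),
    format = format,
    files = sort(files)
  ), class = "fhir_manifest")
  jsonlite::write_json(unclass(manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# FHIR XML: every primitive becomes an element with a `value` attribute,
# objects nest, arrays repeat the element name; the resource type is the
# root element in the FHIR namespace.
write_fhir_xml <- function(resource, path) {
  doc <- xml2::xml_new_root(resource$resourceType,
                            xmlns = "http://hl7.org/fhir")
  body <- unclass(resource)
  body$resourceType <- NULL
  add_fhir_xml_children(doc, body)
  xml2::write_xml(doc, path)
  invisible(path)
}

add_fhir_xml_children <- function(node, x) {
  for (nm in names(x)) {
    val <- x[[nm]]
    if (is.list(val) && (is.null(names(val)) || !any(nzchar(names(val))))) {
      for (item in val) add_fhir_xml_one(node, nm, item)
    } else {
      add_fhir_xml_one(node, nm, val)
    }
  }
}

add_fhir_xml_one <- function(node, nm, val) {
  child <- xml2::xml_add_child(node, nm)
  if (is.list(val)) {
    add_fhir_xml_children(child, val)
  } else {
    xml2::xml_set_attr(child, "value", fhir_scalar_chr(val))
  }
}

fhir_scalar_chr <- function(v) {
  if (is.logical(v)) tolower(as.character(v))
  else if (is.numeric(v)) format(v, digits = 15, scientific = FALSE,
                                 trim = TRUE)
  else as.character(v)
}

#' Read resources back from a serialized output directory
#'
#' @param out_dir Directory written by [serialize_resources()].
#' @return Named list of resource lists keyed by domain file name.
#' @export
read_fhir_ndjson <- function(out_dir) {
  files <- sort(list.files(out_dir, pattern = "\\.ndjson$",
                           full.names = TRUE))
  out <- list()
  for (f in files) {
    nm <- sub("\\.ndjson$", "", basename(f))
    lines <- readLines(f, warn = FALSE)
    out[[nm]] <- map(seq_along(lines), function(i) {
      parsed <- tryCatch(
        jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
        error = function(e) NULL)
      if (is.null(parsed)) {
        abort(paste0("Malformed resource in ", basename(f), " line ", i))
      }
      parsed
    })
  }
  out
}

#' @export
print.fhir_manifest <- function(x, ...) {
  cat("<fhir_manifest> format:", x$format, "\n resource counts:\n")
  for (nm in names(x$resource_counts)) {
    cat(sprintf("   %-18s %6d\n", nm, x$resource_counts[[nm]]))
  }
  if (length(x$crosswalk_misses)) {
    cat(" crosswalk misses:\n")
    for (nm in names(x$crosswalk_misses)) {
      cat(sprintf("   %-30s %6d\n", nm, x$crosswalk_misses[[nm]]))
    }
  }
  invisible(x)
}

#' Plot per-type resource counts of a manifest
#'
#' @param object A `fhir_manifest`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fhir_manifest <- function(object, ...) {
  tb <- tibble(type = names(object$resource_counts),
               n = unlist(object$resource_counts))
  ggplot2::ggplot(tb, ggplot2::aes(x = stats::reorder(.data$type, .data$n),
                                   y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "resources emitted",
                  title = "FHIR resources by type") +
    ggplot2::theme_minimal()
}
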