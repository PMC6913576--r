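# Table-driven STU3 structural validation. The element tables live in
# inst/extdata/stu3_structure.json (a snapshot of the published 3.0.1
# resource definitions for the 7 supported types) and are interpreted here
# by a generic walker, so the check stays independent of how the emitter
# happens to assemble its resources.

.stu3_cache <- new.env(parent = emptyenv())

stu3_structure <- function() {
  if (is.null(.stu3_cache$def)) {
    path <- system.file("extdata", "stu3_structure.json",
                        package = "cdm2fhir", mustWork = TRUE)
    .stu3_cache$def <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  .stu3_cache$def
}

is_scalar_chr <- function(v) is.character(v) && length(v) == 1L && !is.na(v)

check_primitive <- function(v, type, spec, path) {
  issues <- character()
  bad <- function(msg) paste0(path, ": ", msg)
  switch(type,
    string = , uri = {
      if (!is_scalar_chr(v) || !nzchar(v)) {
        issues <- c(issues, bad("must be a non-empty string"))
      }
    },
    code = {
      if (!is_scalar_chr(v) || grepl("^\\s|\\s$", v) || !nzchar(v)) {
        issues <- c(issues, bad("must be a code without surrounding whitespace"))
      } else if (!is.null(spec$enum) &&
                 !v %in% unlist(spec$enum)) {
        issues <- c(issues, bad(paste0("code '", v, "' not in the required value set")))
      }
    },
    id = {
      if (!is_scalar_chr(v) || !grepl("^[A-Za-z0-9.-]{1,64}$", v)) {
        issues <- c(issues, bad("must match [A-Za-z0-9.-]{1,64}"))
      }
    },
    date = {
      if (!is_scalar_chr(v) || !grepl("^\\d{4}(-\\d{2}(-\\d{2})?)?$", v)) {
        issues <- c(issues, bad("must be a date (YYYY[-MM[-DD]])"))
      }
    },
    dateTime = {
      if (!is_scalar_chr(v) ||
          !grepl("^\\d{4}(-\\d{2}(-\\d{2}(T\\d{2}:\\d{2}:\\d{2}(\\.\\d+)?(Z|[+-]\\d{2}:\\d{2})?)?)?)?$", v)) {
        issues <- c(issues, bad("must be a dateTime"))
      }
    },
    instant = {
      if (!is_scalar_chr(v) ||
          !grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}(\\.\\d+)?(Z|[+-]\\d{2}:\\d{2})$", v)) {
        issues <- c(issues, bad("must be an instant with time and zone"))
      }
    },
    boolean = {
      if (!(is.logical(v) && length(v) == 1L && !is.na(v))) {
        issues <- c(issues, bad("must be a boolean"))
      }
    },
    decimal = {
      if (!(is.numeric(v) && length(v) == 1L && !is.na(v))) {
        issues <- c(issues, bad("must be a decimal"))
      }
    },
    `reference-string` = {
      if (!is_scalar_chr(v) ||
          !grepl("^[A-Za-z]+/[A-Za-z0-9.-]{1,64}$", v)) {
        issues <- c(issues, bad("must be '<Type>/<id>'"))
      }
    },
    issues <- c(issues, bad(paste0("unknown primitive type ", type)))
  )
  issues
}

check_complex <- function(v, type_name, def, path) {
  spec <- def$types[[type_name]]
  if (is.null(spec)) {
    return(paste0(path, ": unknown complex type ", type_name))
  }
  issues <- check_elements(v, spec$elements, def, path)
  # every coded element carries (system, code) together or is absent
  if (type_name == "Coding") {
    has_sys <- !is.null(v$system); has_code <- !is.null(v$code)
    if (xor(has_sys, has_code)) {
      issues <- c(issues, paste0(path, ": Coding must carry system and code together"))
    }
  }
  issues
}

check_elements <- function(obj, elements, def, path) {
  issues <- character()
  if (!is.list(obj) || is.null(names(obj))) {
    return(paste0(path, ": must be an object"))
  }
  unknown <- setdiff(names(obj), names(elements))
  if (length(unknown)) {
    issues <- c(issues, paste0(path, ": unknown element(s): ",
                               paste(unknown, collapse = ", ")))
  }
  for (nm in names(elements)) {
    spec <- elements[[nm]]
    v <- obj[[nm]]
    epath <- paste0(path, ".", nm)
    if (is.null(v)) {
      if (isTRUE(spec$required)) {
        issues <- c(issues, paste0(epath, ": required element missing"))
      }
      next
    }
    # explicit nulls are forbidden: serialized resources carry no
    # null-valued elements
    if (length(v) == 1L && !is.list(v) && is.na(v)) {
      issues <- c(issues, paste0(epath, ": null value not allowed"))
      next
    }
    items <- if (isTRUE(spec$array)) {
      if (!is.list(v) || (length(v) && !is.null(names(v)) &&
                          any(nzchar(names(v))))) {
        issues <- c(issues, paste0(epath, ": must be an array"))
        next
      }
      v
    } else list(v)
    for (i in seq_along(items)) {
      ipath <- if (isTRUE(spec$array)) paste0(epath, "[", i, "]") else epath
      item <- items[[i]]
      if (spec$type %in% names(def$types)) {
        issues <- c(issues, check_complex(item, spec$type, def, ipath))
      } else {
        issues <- c(issues, check_primitive(item, spec$type, spec, ipath))
      }
    }
  }
  issues
}

#' Structurally validate a FHIR STU3 resource
#'
#' Checks one resource (a nested list, e.g. a parsed NDJSON line or the
#' output of [emit_domain()]) against the bundled STU3 structural-definition
#' snapshot: known resource type, no unknown elements, required elements
#' present, primitive value shapes (codes, dates, instants, ids, reference
#' strings), array cardinality, codings carrying system and code together,
#' and no null-valued elements.
#'
#' @param resource A resource as a nested named list.
#' @return Character vector of issues; empty when the resource is valid.
#' @export
#' @examples
#' validate_stu3(list(resourceType = "Patient", id = "p1", gender = "female"))
validate_stu3 <- function(resource) {
  def <- stu3_structure()
  if (!is.list(resource)) return("resource must be a list")
  type <- resource$resourceType
  if (is.null(type) || !type %in% names(def$resources)) {
    return(paste0("unsupported or missing resourceType: ",
                  type %||% "<none>"))
  }
  body <- unclass(resource)
  body$resourceType <- NULL
  check_elements(body, def$resources[[type]]$elements, def, type)
}

#' Validate every resource in a set
#'
#' @param resource_sets Named list of resource lists (per domain), e.g. from
#'   [read_fhir_ndjson()] or [emit_domain()].
#' @return Tibble with one row per resource: `domain`, `id`, `valid`,
#'   `n_issues`, `issues` (list-column).
#' @export
validate_stu3_all <- function(resource_sets) {
  list_rbind(imap(resource_sets, function(res, nm) {
    if (!length(res)) return(tibble())
    tibble(
      domain = nm,
      id = map_chr(res, function(r) r$id %||% NA_character_),
      issues = map(res, validate_stu3)
    ) |>
      mutate(n_issues = map_int(.data$issues, length),
             valid = .data$n_issues == 0L)
  }))
}
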