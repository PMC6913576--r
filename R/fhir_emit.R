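# View rows -> in-memory FHIR STU3 resources (nested named lists, ready for
# JSON/XML serialization). Elements with no source value are absent, never
# null-valued. Fixed status codes are supplied where STU3 requires a status
# the source models do not carry: Observation "final", Encounter "finished",
# Procedure "completed", MedicationRequest intent "order" / status
# "completed".

fhir_resource_types <- c("Patient", "Encounter", "Condition", "Procedure",
                         "Observation", "MedicationRequest", "Practitioner")

fhir_date <- function(d) {
  if (is.null(d) || is.na(d)) return(NULL)
  format(as.Date(d), "%Y-%m-%d")
}

# STU3 `instant` needs time and zone; timezone-naive source dates are
# rendered as midnight UTC.
fhir_instant <- function(d) {
  fd <- fhir_date(d)
  if (is.null(fd)) NULL else paste0(fd, "T00:00:00Z")
}

#' Sanitize a view identifier into a legal FHIR id
#'
#' STU3 ids admit only `[A-Za-z0-9.-]`, at most 64 characters. Composite
#' view identifiers can contain colons (concept prefixes); illegal
#' characters are replaced by `"."`. Over-long ids are truncated with a
#' short content-hash suffix to stay unique. References use the sanitized id
#' consistently.
#'
#' @param x Character vector of raw identifiers.
#' @return Character vector of legal FHIR ids.
#' @export
#' @examples
#' sanitize_fhir_id("123-456-P9-05-JAN-2019-LOINC:2345-7-1")
sanitize_fhir_id <- function(x) {
  out <- gsub("[^A-Za-z0-9.-]", ".", x)
  long <- !is.na(out) & nchar(out) > 64L
  if (any(long)) {
    out[long] <- vapply(which(long), function(i) {
      paste0(substr(out[i], 1L, 55L), ".",
             substr(rlang::hash(x[i]), 1L, 8L))
    }, character(1))
  }
  out
}

sanitize_reference <- function(ref) {
  if (is.null(ref) || is.na(ref)) return(NULL)
  slash <- regexpr("/", ref, fixed = TRUE)
  if (slash < 0) return(sanitize_fhir_id(ref))
  paste0(substr(ref, 1, slash), sanitize_fhir_id(substring(ref, slash + 1L)))
}

chr1 <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x)) NULL else as.character(x)
}
num1 <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x)) NULL else as.numeric(x)
}

drop_null <- function(x) x[!vapply(x, is.null, logical(1))]

coding <- function(system, code, display = NULL) {
  system <- chr1(system); code <- chr1(code)
  if (is.null(system) || is.null(code)) return(NULL)
  drop_null(list(system = system, code = code, display = chr1(display)))
}

codeable <- function(system, code, display = NULL) {
  cd <- coding(system, code, display)
  if (is.null(cd)) NULL else list(coding = list(cd))
}

reference <- function(ref) {
  ref <- chr1(ref)
  if (is.null(ref)) NULL else list(reference = sanitize_reference(ref))
}

identifier_of <- function(value) {
  value <- chr1(value)
  if (is.null(value)) NULL else list(list(value = value))
}

new_resource <- function(type, id, body) {
  out <- c(list(resourceType = type, id = sanitize_fhir_id(id)),
           drop_null(body))
  structure(out, class = c("fhir_resource", "list"))
}

#' Emit one Observation resource from an observation view row
#'
#' `valueQuantity` is populated (value, comparator, unit) when a numeric
#' value exists, `valueString` only when the row carries text, and
#' `valueCodeableConcept` for coded values (smoking status); textual
#' reference-range bounds go to `referenceRange.text`. Any element whose
#' source field is empty is absent from the resource.
#'
#' @param row A single observation view row as a named list (one row of the
#'   labs or vitals view).
#' @return A `fhir_resource` list, or `NULL` when the row has no identifier,
#'   subject or code.
#' @export
emit_observation <- function(row) {
  if (is.null(chr1(row$obs_identifier)) ||
      is.null(chr1(row$obs_subject_reference)) ||
      is.null(chr1(row$obs_code_coding_code))) {
    return(NULL)
  }
  vq <- NULL
  if (!is.null(num1(row$obs_valuequantity_value))) {
    vq <- drop_null(list(
      value = num1(row$obs_valuequantity_value),
      comparator = chr1(row$obs_valuequantity_comparator),
      unit = chr1(row$obs_valuequantity_code)
    ))
  }
  rr_text <- c(chr1(row$obs_refrange_low), chr1(row$obs_refrange_high))
  rr <- if (length(rr_text)) {
    list(list(text = paste(rr_text, collapse = " - ")))
  } else NULL
  new_resource("Observation", row$obs_identifier, list(
    identifier = identifier_of(row$obs_identifier),
    status = "final",
    category = list(codeable(row$obs_category_syst, row$obs_category_code,
                             row$obs_category_display)),
    code = codeable(row$obs_code_coding_syst, row$obs_code_coding_code,
                    row$obs_code_coding_display),
    subject = reference(row$obs_subject_reference),
    context = reference(row$obs_context_reference),
    effectiveDateTime = fhir_date(row$obs_effectivedatetime),
    issued = fhir_instant(row$obs_issued),
    valueQuantity = vq,
    valueString = chr1(row$obs_valuestring),
    valueCodeableConcept = codeable(row$obs_valuecodeableconcept_syst,
                                    row$obs_valuecodeableconcept_code),
    interpretation = codeable(row$obs_interpretation_syst,
                              row$obs_interpretation_code),
    referenceRange = rr
  ))
}

emit_patient <- function(row) {
  if (is.null(chr1(row$pat_identifier))) return(NULL)
  ext <- list()
  race <- coding(row$pat_race_syst, row$pat_race_code)
  if (!is.null(race)) {
    ext <- c(ext, list(list(
      url = "http://hl7.org/fhir/us/core/StructureDefinition/us-core-race",
      extension = list(list(url = "ombCategory", valueCoding = race)))))
  }
  eth <- coding(row$pat_ethnicity_syst, row$pat_ethnicity_code)
  if (!is.null(eth)) {
    ext <- c(ext, list(list(
      url = "http://hl7.org/fhir/us/core/StructureDefinition/us-core-ethnicity",
      extension = list(list(url = "ombCategory", valueCoding = eth)))))
  }
  deceased <- row$pat_deceased
  new_resource("Patient", row$pat_identifier, list(
    identifier = identifier_of(row$pat_identifier),
    extension = if (length(ext)) ext else NULL,
    gender = chr1(row$pat_gender_code),
    birthDate = fhir_date(row$pat_birthdate),
    deceasedBoolean = if (is.null(deceased) || is.na(deceased)) NULL
                      else isTRUE(deceased)
  ))
}

emit_encounter <- function(row) {
  if (is.null(chr1(row$enc_identifier)) ||
      is.null(chr1(row$enc_subject_reference))) {
    return(NULL)
  }
  period <- drop_null(list(start = fhir_date(row$enc_period_start),
                           end = fhir_date(row$enc_period_end)))
  hosp <- drop_null(list(
    admitSource = codeable(row$enc_admitsource_syst,
                           row$enc_admitsource_code),
    dischargeDisposition = codeable(row$enc_dischargedisposition_syst,
                                    row$enc_dischargedisposition_code)
  ))
  new_resource("Encounter", row$enc_identifier, list(
    identifier = identifier_of(row$enc_identifier),
    status = "finished",
    class = coding(row$enc_class_syst, row$enc_class_code),
    subject = reference(row$enc_subject_reference),
    period = if (length(period)) period else NULL,
    hospitalization = if (length(hosp)) hosp else NULL
  ))
}

emit_condition <- function(row) {
  if (is.null(chr1(row$cond_identifier)) ||
      is.null(chr1(row$cond_subject_reference)) ||
      is.null(chr1(row$cond_code_coding_code))) {
    return(NULL)
  }
  new_resource("Condition", row$cond_identifier, list(
    identifier = identifier_of(row$cond_identifier),
    code = codeable(row$cond_code_coding_syst, row$cond_code_coding_code,
                    row$cond_code_coding_display),
    subject = reference(row$cond_subject_reference),
    context = reference(row$cond_context_reference),
    onsetDateTime = fhir_date(row$cond_onsetdatetime)
  ))
}

emit_procedure <- function(row) {
  if (is.null(chr1(row$proc_identifier)) ||
      is.null(chr1(row$proc_subject_reference)) ||
      is.null(chr1(row$proc_code_coding_code))) {
    return(NULL)
  }
  new_resource("Procedure", row$proc_identifier, list(
    identifier = identifier_of(row$proc_identifier),
    status = "completed",
    code = codeable(row$proc_code_coding_syst, row$proc_code_coding_code,
                    row$proc_code_coding_display),
    subject = reference(row$proc_subject_reference),
    context = reference(row$proc_context_reference),
    performedDateTime = fhir_date(row$proc_performeddatetime)
  ))
}

emit_medicationrequest <- function(row) {
  if (is.null(chr1(row$medreq_identifier)) ||
      is.null(chr1(row$medreq_subject_reference)) ||
      is.null(chr1(row$medreq_medication_code))) {
    return(NULL)
  }
  new_resource("MedicationRequest", row$medreq_identifier, list(
    identifier = identifier_of(row$medreq_identifier),
    status = "completed",
    intent = "order",
    medicationCodeableConcept = codeable(row$medreq_medication_syst,
                                         row$medreq_medication_code,
                                         row$medreq_medication_display),
    subject = reference(row$medreq_subject_reference),
    context = reference(row$medreq_context_reference),
    authoredOn = fhir_date(row$medreq_authoredon)
  ))
}

emit_practitioner <- function(row) {
  if (is.null(chr1(row$pract_identifier))) return(NULL)
  name <- chr1(row$pract_name)
  new_resource("Practitioner", row$pract_identifier, list(
    identifier = identifier_of(row$pract_identifier),
    name = if (is.null(name)) NULL else list(list(text = name))
  ))
}

.domain_emitters <- list(
  patient = emit_patient,
  encounter = emit_encounter,
  condition = emit_condition,
  procedure = emit_procedure,
  observation = emit_observation,
  medicationrequest = emit_medicationrequest,
  practitioner = emit_practitioner
)

#' Emit FHIR resources for one view
#'
#' One resource per well-formed view row, in deterministic identifier
#' order; rows missing an identifier, subject or code are skipped and
#' tallied in the `skipped` attribute.
#'
#' @param rows A view tibble (from one of the `build_*_view()` functions).
#' @param domain One of `"patient"`, `"encounter"`, `"condition"`,
#'   `"procedure"`, `"observation"`, `"medicationrequest"`,
#'   `"practitioner"`.
#' @return List of `fhir_resource` objects with attribute `skipped` (rows
#'   dropped at emission).
#' @export
emit_domain <- function(rows, domain) {
  domain <- match.arg(domain, names(.domain_emitters))
  emitter <- .domain_emitters[[domain]]
  if (nrow(rows) == 0L) {
    return(structure(list(), skipped = 0L))
  }
  prepared <- rows
  for (cn in names(prepared)) {
    if (inherits(prepared[[cn]], "Date")) {
      prepared[[cn]] <- format(prepared[[cn]], "%Y-%m-%d")
    }
  }
  out <- purrr::pmap(prepared, function(...) emitter(list(...)))
  keep <- !vapply(out, is.null, logical(1))
  structure(out[keep], skipped = sum(!keep))
}

#' @export
print.fhir_resource <- function(x, ...) {
  cat(jsonlite::toJSON(unclass(x), auto_unbox = TRUE, pretty = TRUE,
                       digits = NA), "\n")
  invisible(x)
}
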