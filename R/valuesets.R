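# Bundled reference value sets: offline snapshots of the FHIR STU3 (3.0.1)
# value sets the starter crosswalks target, plus the PCORnet CDM v4.1 local
# sets for the two encounter fields whose granularity FHIR cannot fully
# carry. Shipped as a versioned CSV under inst/extdata.

.valueset_aliases <- list(
  # The i2b2 starter crosswalk carries the ActEncounterCode system exactly as
  # the documentation URL; treat it as an alias of the canonical v3 system.
  "https://hl7.org/fhir/STU3/v3/ActEncounterCode/vs.html" =
    "http://hl7.org/fhir/v3/ActCode",
  "http://hl7.org/fhir/ValueSet/observation-interpretation" =
    "http://hl7.org/fhir/v2/0078"
)

canonical_system <- function(system) {
  hit <- .valueset_aliases[[system]]
  if (is.null(hit)) system else hit
}

.valueset_cache <- new.env(parent = emptyenv())

#' Bundled reference value sets
#'
#' Returns the package's offline snapshot of the value sets used by the
#' starter crosswalks: FHIR STU3 encounter class (ActEncounterCode),
#' discharge disposition, admitting source, observation interpretation,
#' quantity comparator, administrative gender, the CDC race/ethnicity codes,
#' a SNOMED CT smoking-status subset, and the PCORnet v4.1 local
#' DISCHARGE_STATUS and ADMITTING_SOURCE sets.
#'
#' @return A tibble with columns `valueset`, `system`, `code`, `display`.
#' @export
#' @examples
#' dplyr::count(reference_valuesets(), valueset)
reference_valuesets <- function() {
  if (is.null(.valueset_cache$tb)) {
    path <- system.file("extdata", "reference_valuesets.csv",
                        package = "cdm2fhir", mustWork = TRUE)
    .valueset_cache$tb <- readr::read_csv(
      path, col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
  }
  .valueset_cache$tb
}

#' Codes of one bundled reference value set
#'
#' @param name Value-set identifier, e.g. `"encounter-class"` or
#'   `"pcornet-discharge-status"`.
#' @return Character vector of admissible codes.
#' @export
valueset_codes <- function(name) {
  tb <- reference_valuesets()
  codes <- tb$code[tb$valueset == name]
  if (!length(codes)) abort(paste0("No bundled value set named: ", name))
  codes
}

# codes admissible for a (canonical) system URI; NULL when the system has no
# bundled snapshot (nothing to check against).
system_codes <- function(system) {
  tb <- reference_valuesets()
  hit <- tb$code[tb$system == canonical_system(system)]
  if (length(hit)) hit else NULL
}
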