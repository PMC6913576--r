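#' Build every view for a source table set
#'
#' Runs all eight view builders (patient, encounter, condition, procedure,
#' labs, vitals, medication request, practitioner) against one source table
#' set and crosswalk. Identical inputs give byte-identical views.
#'
#' @param sts A `source_table_set`.
#' @param xw A `fhir_crosswalk`.
#' @param lab_code_prefix,dx_code_prefix,px_code_prefix,rx_code_prefix,vital_code_prefix
#'   i2b2 concept-code prefixes per domain (ignored for PCORnet input).
#' @param strip_prefix Drop `"LOINC:"`-style prefixes from i2b2 codes so
#'   they compare directly with codes from prefix-free models.
#' @param clean_ref_ranges Emit bare reference-range bounds (PCORnet labs).
#' @return Named list of view tibbles: `patient`, `encounter`, `condition`,
#'   `procedure`, `observation_labs`, `observation_vitals`,
#'   `medicationrequest`, `practitioner`.
#' @export
#' @examples
#' stream <- generate_event_stream(cohort_spec(n_patients = 3, seed = 1))
#' views <- build_views(render_pcornet(stream),
#'                      load_crosswalk(starter_crosswalk_path("pcornet")))
#' names(views)
build_views <- function(sts, xw,
                        lab_code_prefix = "LOINC",
                        dx_code_prefix = "ICD10",
                        px_code_prefix = "CPT",
                        rx_code_prefix = "RXNORM",
                        vital_code_prefix = "VITAL",
                        strip_prefix = FALSE,
                        clean_ref_ranges = FALSE) {
  labs <- if (sts$model == "i2b2") {
    build_labs_view_i2b2(sts, lab_code_prefix, strip_prefix)
  } else {
    build_labs_view_pcornet(sts, xw, clean_ref_ranges)
  }
  list(
    patient = build_patient_view(sts, xw),
    encounter = build_encounter_view(sts, xw),
    condition = build_condition_view(sts, xw, dx_code_prefix, strip_prefix),
    procedure = build_procedure_view(sts, xw, px_code_prefix, strip_prefix),
    observation_labs = labs,
    observation_vitals = build_vitals_view(sts, xw, vital_code_prefix),
    medicationrequest = build_medrequest_view(sts, xw, rx_code_prefix,
                                              strip_prefix),
    practitioner = build_practitioner_view(sts, xw)
  )
}

#' Write views to CSV for inspection
#'
#' Each view is written with its DOMAINPREFIX_FIELD headers upper-cased,
#' mirroring the staging-view convention.
#'
#' @param views Result of [build_views()].
#' @param dir_path Output directory.
#' @return `dir_path`, invisibly.
#' @export
dump_views <- function(views, dir_path) {
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(views)) {
    tb <- views[[nm]]
    names(tb) <- toupper(names(tb))
    for (cn in names(tb)) {
      if (inherits(tb[[cn]], "Date")) tb[[cn]] <- format(tb[[cn]], "%Y-%m-%d")
    }
    readr::write_csv(tb, file.path(dir_path, paste0("view_", nm, ".csv")),
                     na = "", progress = FALSE)
  }
  invisible(dir_path)
}

view_skip_summary <- function(views) {
  list_rbind(imap(views, function(v, nm) {
    sk <- attr(v, "skipped")
    if (is.null(sk) || nrow(sk) == 0L) return(tibble())
    mutate(sk, domain = nm, .before = 1)
  }))
}
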