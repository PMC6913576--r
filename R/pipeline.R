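#' Run configuration for a transformation
#'
#' Resolves the options of one end-to-end run. Precedence when used from the
#' command line: flag > YAML config file > built-in default.
#'
#' @param model `"i2b2"` or `"pcornet"`.
#' @param input_dir Directory of source CSV tables.
#' @param output_dir Directory for FHIR output.
#' @param crosswalk_path Crosswalk CSV ([starter_crosswalk_path()] default
#'   by model).
#' @param cohort_file Optional cohort file (one patient id per line).
#' @param format `"json"` or `"xml"`.
#' @param strip_code_prefix Drop `"LOINC:"`-style prefixes from i2b2 codes.
#' @param clean_ref_ranges Emit bare reference-range bounds.
#' @param bundle Wrap JSON output in one collection Bundle.
#' @param dump_views Also write each intermediate view as CSV.
#' @param lab_code_prefix,dx_code_prefix,px_code_prefix,rx_code_prefix,vital_code_prefix
#'   i2b2 concept-code prefixes.
#' @return A `run_config` list.
#' @export
run_config <- function(model, input_dir, output_dir,
                       crosswalk_path = starter_crosswalk_path(model),
                       cohort_file = NULL, format = "json",
                       strip_code_prefix = FALSE, clean_ref_ranges = FALSE,
                       bundle = FALSE, dump_views = FALSE,
                       lab_code_prefix = "LOINC", dx_code_prefix = "ICD10",
                       px_code_prefix = "CPT", rx_code_prefix = "RXNORM",
                       vital_code_prefix = "VITAL") {
  model <- match.arg(model, c("i2b2", "pcornet"))
  format <- match.arg(format, c("json", "xml"))
  structure(list(
    model = model, input_dir = input_dir, output_dir = output_dir,
    crosswalk_path = crosswalk_path, cohort_file = cohort_file,
    format = format, strip_code_prefix = strip_code_prefix,
    clean_ref_ranges = clean_ref_ranges, bundle = bundle,
    dump_views = dump_views, lab_code_prefix = lab_code_prefix,
    dx_code_prefix = dx_code_prefix, px_code_prefix = px_code_prefix,
    rx_code_prefix = rx_code_prefix, vital_code_prefix = vital_code_prefix
  ), class = "run_config")
}

#' Transform a loaded source table set to serialized FHIR output
#'
#' The core load-free pipeline: build all views, emit the seven resource
#' types (patients, encounters and practitioners first, so every reference
#' in the output points at a resource emitted in the same run), serialize,
#' and write the manifest.
#'
#' @param sts A `source_table_set`.
#' @param xw A `fhir_crosswalk`.
#' @param out_dir Output directory.
#' @param format `"json"` or `"xml"`.
#' @param bundle,dump_views,strip_prefix,clean_ref_ranges,... Passed through
#'   to [build_views()] / [serialize_resources()].
#' @return The run manifest (`fhir_manifest`), invisibly.
#' @export
#' @examples
#' stream <- generate_event_stream(cohort_spec(n_patients = 3, seed = 1))
#' out <- file.path(tempdir(), "fhir3")
#' transform_source(render_pcornet(stream),
#'                  load_crosswalk(starter_crosswalk_path("pcornet")), out)
transform_source <- function(sts, xw, out_dir, format = "json",
                             bundle = FALSE, dump_views = FALSE,
                             strip_prefix = FALSE, clean_ref_ranges = FALSE,
                             ...) {
  reset_misses(xw)
  views <- build_views(sts, xw, strip_prefix = strip_prefix,
                       clean_ref_ranges = clean_ref_ranges, ...)
  if (dump_views) dump_views(views, file.path(out_dir, "views"))
  resources <- list(
    patient = emit_domain(views$patient, "patient"),
    encounter = emit_domain(views$encounter, "encounter"),
    practitioner = emit_domain(views$practitioner, "practitioner"),
    condition = emit_domain(views$condition, "condition"),
    procedure = emit_domain(views$procedure, "procedure"),
    observation_labs = emit_domain(views$observation_labs, "observation"),
    observation_vitals = emit_domain(views$observation_vitals, "observation"),
    medicationrequest = emit_domain(views$medicationrequest,
                                    "medicationrequest")
  )
  serialize_resources(resources, out_dir, format = format, bundle = bundle,
                      crosswalk_misses = crosswalk_misses(xw),
                      view_skips = view_skip_summary(views))
}

#' Run a full transformation from a configuration
#'
#' Load, validate, build views, emit and serialize in one call.
#'
#' @param config A [run_config()].
#' @return The run manifest, invisibly.
#' @export
run_transform <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sts <- load_source(config$input_dir, config$model,
                     cohort_file = config$cohort_file)
  xw <- load_crosswalk(config$crosswalk_path)
  transform_source(
    sts, xw, config$output_dir, format = config$format,
    bundle = config$bundle, dump_views = config$dump_views,
    strip_prefix = config$strip_code_prefix,
    clean_ref_ranges = config$clean_ref_ranges,
    lab_code_prefix = config$lab_code_prefix,
    dx_code_prefix = config$dx_code_prefix,
    px_code_prefix = config$px_code_prefix,
    rx_code_prefix = config$rx_code_prefix,
    vital_code_prefix = config$vital_code_prefix
  )
}

#' Run the summary-statistics validation protocol end to end
#'
#' Flattens a source table directory and a FHIR output directory to
#' per-variable extracts, summarizes both, and compares them.
#'
#' @param source_dir Directory of source CSV tables.
#' @param model `"i2b2"` or `"pcornet"`.
#' @param fhir_dir Directory of NDJSON output.
#' @param crosswalk_path Crosswalk CSV used for the run.
#' @param tolerance Relative numeric tolerance for [compare_summaries()].
#' @param med_code_map Optional medication id translation (see
#'   [flatten_source()]).
#' @return A `validation_report`.
#' @export
run_validation <- function(source_dir, model, fhir_dir,
                           crosswalk_path = starter_crosswalk_path(model),
                           tolerance = 1e-9, med_code_map = NULL) {
  sts <- load_source(source_dir, model)
  xw <- load_crosswalk(crosswalk_path)
  src <- summarize_extract(flatten_source(sts, xw,
                                          med_code_map = med_code_map))
  fhir <- summarize_extract(flatten_fhir(fhir_dir))
  compare_summaries(src, fhir, tolerance = tolerance)
}
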