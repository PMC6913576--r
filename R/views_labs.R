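# Laboratory views: the normalized intermediate records that decouple the
# source model from FHIR emission. One builder per source model; both emit
# the same OBS_* column roster (see `obs_view_cols`).

obs_view_cols <- c(
  "obs_identifier", "obs_subject_reference", "obs_context_reference",
  "obs_category_syst", "obs_category_code", "obs_category_display",
  "obs_code_coding_syst", "obs_code_coding_code", "obs_code_coding_display",
  "obs_valuequantity_value", "obs_valuequantity_comparator",
  "obs_valuequantity_code",
  "obs_valuecodeableconcept_syst", "obs_valuecodeableconcept_code",
  "obs_valuestring", "obs_issued", "obs_effectivedatetime",
  "obs_refrange_low", "obs_refrange_high",
  "obs_interpretation_code", "obs_interpretation_syst"
)

# Fixed upper-case English month abbreviations: the identifier must not
# depend on the session locale.
.months_upper <- c("JAN", "FEB", "MAR", "APR", "MAY", "JUN",
                   "JUL", "AUG", "SEP", "OCT", "NOV", "DEC")

format_date_dmony <- function(d) {
  d <- as.Date(d)
  out <- rep(NA_character_, length(d))
  ok <- !is.na(d)
  lt <- as.POSIXlt(d[ok])
  out[ok] <- sprintf("%02d-%s-%04d", lt$mday, .months_upper[lt$mon + 1L],
                     lt$year + 1900L)
  out
}

#' Build the composite observation identifier
#'
#' Hyphen-joined concatenation of patient id, encounter id, provider id, the
#' fact date rendered as `DD-MON-YYYY` (zero-padded day, upper-case 3-letter
#' English month), the concept code and the repeat index. Any missing part
#' yields `NA` (the calling view skips and logs such rows).
#'
#' @param patient_num,encounter_num,provider_id Source identifiers.
#' @param start_date Fact date (`Date` or ISO string).
#' @param concept_cd Concept code (emitted verbatim, prefix included).
#' @param instance_num Repeat index.
#' @return Character vector of identifiers (`NA` where a part is missing).
#' @export
#' @examples
#' build_obs_identifier(123, 456, "P9", as.Date("2019-01-05"), "LOINC:2345-7", 1)
build_obs_identifier <- function(patient_num, encounter_num, provider_id,
                                 start_date, concept_cd, instance_num) {
  date_piece <- format_date_dmony(start_date)
  parts <- list(as.character(patient_num), as.character(encounter_num),
                as.character(provider_id), date_piece,
                as.character(concept_cd), as.character(instance_num))
  any_na <- Reduce(`|`, lapply(parts, is.na))
  out <- do.call(paste, c(parts, sep = "-"))
  out[any_na] <- NA_character_
  out
}

#' Map i2b2 value-type flags to a FHIR quantity comparator
#'
#' Only numeric facts (`valtype_cd == "N"`) carry comparator flags in
#' `tval_char`: `L` is `<`, `G` is `>`, `LE` is `<=`, `GE` is `>=`, and `E`
#' (equals) maps to no comparator. Every other combination yields `NA`.
#'
#' @param valtype_cd,tval_char Vectors of the two i2b2 flags.
#' @return Character vector of comparators (`<`, `<=`, `>`, `>=`) or `NA`.
#' @export
map_i2b2_comparator <- function(valtype_cd, tval_char) {
  out <- rep(NA_character_, length(valtype_cd))
  num <- !is.na(valtype_cd) & valtype_cd == "N" & !is.na(tval_char)
  out[num & tval_char == "L"] <- "<"
  out[num & tval_char == "G"] <- ">"
  out[num & tval_char == "LE"] <- "<="
  out[num & tval_char == "GE"] <- ">="
  out
}

strip_code_prefix <- function(code) sub("^[^:]+:", "", code)

finish_view <- function(view, id_col, n_input, n_no_visit = 0L) {
  n_bad_id <- sum(is.na(view[[id_col]]))
  view <- view[!is.na(view[[id_col]]), , drop = FALSE]
  n_pre <- nrow(view)
  view <- distinct(view)
  view <- arrange(view, .data[[id_col]])
  skipped <- tibble(
    reason = c("no-visit-row", "missing-identifier-part", "duplicate-row"),
    n = c(as.integer(n_no_visit), as.integer(n_bad_id),
          as.integer(n_pre - nrow(view)))
  )
  attr(view, "skipped") <- skipped[skipped$n > 0L, , drop = FALSE]
  attr(view, "n_input") <- as.integer(n_input)
  view
}

#' Build the laboratory observation view from an i2b2 table set
#'
#' Selects facts whose `CONCEPT_CD` starts with the lab code prefix
#' (default `"LOINC"`), joins the concept dimension for display labels
#' (outer-join: facts without a concept row keep a missing display) and the
#' visit dimension for encounter context (inner-join: facts without a visit
#' row are dropped and logged), then derives one distinct view row per
#' qualifying fact. The concept code is emitted verbatim, prefix included,
#' unless `strip_prefix` is set. `obs_issued` carries the fact date;
#' `obs_effectivedatetime` stays empty.
#'
#' @param sts An i2b2 `source_table_set`.
#' @param lab_code_prefix Concept-code prefix that identifies lab facts.
#' @param strip_prefix Drop the `"LOINC:"`-style prefix from the emitted
#'   code (`FALSE` replicates the source verbatim).
#' @return Tibble of observation view rows; attributes `skipped` (tally of
#'   dropped rows by reason) and `n_input` (qualifying source rows).
#' @export
build_labs_view_i2b2 <- function(sts, lab_code_prefix = "LOINC",
                                 strip_prefix = FALSE) {
  stopifnot(inherits(sts, "source_table_set"), sts$model == "i2b2")
  ofc <- sts$tables$OBSERVATION_FACT
  qualifying <- ofc[!is.na(ofc$CONCEPT_CD) &
                      startsWith(ofc$CONCEPT_CD, lab_code_prefix), ,
                    drop = FALSE]
  n_input <- nrow(qualifying)
  visits <- sts$tables$VISIT_DIMENSION
  joined <- semi_join(qualifying, visits, by = "ENCOUNTER_NUM")
  n_no_visit <- n_input - nrow(joined)
  joined <- left_join(joined, sts$tables$CONCEPT_DIMENSION, by = "CONCEPT_CD")
  code <- joined$CONCEPT_CD
  if (strip_prefix) code <- strip_code_prefix(code)
  view <- tibble(
    obs_identifier = build_obs_identifier(
      joined$PATIENT_NUM, joined$ENCOUNTER_NUM, joined$PROVIDER_ID,
      joined$START_DATE, joined$CONCEPT_CD, joined$INSTANCE_NUM),
    obs_subject_reference = paste0("Patient/", joined$PATIENT_NUM),
    obs_context_reference = paste0("Encounter/", joined$ENCOUNTER_NUM),
    obs_category_syst = fhir_systems$obs_category,
    obs_category_code = "laboratory",
    obs_category_display = "Laboratory",
    obs_code_coding_syst = fhir_systems$loinc,
    obs_code_coding_code = code,
    obs_code_coding_display = joined$NAME_CHAR,
    obs_valuequantity_value = joined$NVAL_NUM,
    obs_valuequantity_comparator =
      map_i2b2_comparator(joined$VALTYPE_CD, joined$TVAL_CHAR),
    obs_valuequantity_code = joined$UNITS_CD,
    obs_valuecodeableconcept_syst = NA_character_,
    obs_valuecodeableconcept_code = NA_character_,
    obs_valuestring = ifelse(!is.na(joined$VALTYPE_CD) &
                               joined$VALTYPE_CD == "T",
                             joined$TVAL_CHAR, NA_character_),
    obs_issued = joined$START_DATE,
    obs_effectivedatetime = as.Date(NA),
    obs_refrange_low = NA_character_,
    obs_refrange_high = NA_character_,
    obs_interpretation_code = NA_character_,
    obs_interpretation_syst = NA_character_
  )
  finish_view(view, "obs_identifier", n_input, n_no_visit)
}

#' Render a PCORnet normal-range bound
#'
#' Concatenates the range modifier in front of the bound for modifiers
#' `EQ`, `GE`, `GT` and `NO` (replicated as stored, including the
#' no-information modifier); any other modifier yields the bare bound.
#' A missing bound yields `NA`.
#'
#' @param modifier,bound Vectors of `NORM_MODIFIER_*` and `NORM_RANGE_*`.
#' @param clean Suppress modifiers and always emit the bare bound.
#' @return Character vector of rendered bounds.
#' @export
#' @examples
#' format_pcornet_ref_range("GE", "3.5")
#' format_pcornet_ref_range("LT", "10")
format_pcornet_ref_range <- function(modifier, bound, clean = FALSE) {
  out <- as.character(bound)
  if (!clean) {
    cat_mod <- !is.na(modifier) & modifier %in% c("EQ", "GE", "GT", "NO") &
      !is.na(bound)
    out[cat_mod] <- paste(modifier[cat_mod], bound[cat_mod])
  }
  out
}

#' Resolve the PCORnet lab result fields that carry sentinel codes
#'
#' The unit is dropped when coded `"NI"` (no information); the qualitative
#' result is dropped when `"NI"` and otherwise falls back to the raw result
#' text when empty; the effective date is the specimen date with the lab
#' order date as fallback.
#'
#' @param result_unit,result_qual,raw_result,specimen_date,lab_order_date
#'   Vectors of the corresponding `LAB_RESULT_CM` columns.
#' @return A list with elements `unit`, `valuestring`, `effective`.
#' @export
resolve_pcornet_result_fields <- function(result_unit, result_qual,
                                          raw_result, specimen_date,
                                          lab_order_date) {
  unit <- ifelse(!is.na(result_unit) & result_unit == "NI",
                 NA_character_, result_unit)
  valuestring <- dplyr::coalesce(result_qual, raw_result)
  valuestring[!is.na(result_qual) & result_qual == "NI"] <- NA_character_
  effective <- dplyr::coalesce(as.Date(specimen_date), as.Date(lab_order_date))
  list(unit = unit, valuestring = valuestring, effective = effective)
}

#' Build the laboratory observation view from a PCORnet table set
#'
#' One distinct view row per `LAB_RESULT_CM` record. The comparator and the
#' interpretation code come from crosswalk lookups on `RESULT_MODIFIER` and
#' `ABN_IND` (outer-join semantics: a miss leaves the field empty); units,
#' qualitative results and the effective date follow the sentinel rules of
#' [resolve_pcornet_result_fields()]; reference ranges are rendered by
#' [format_pcornet_ref_range()].
#'
#' @param sts A PCORnet `source_table_set`.
#' @param xw A `fhir_crosswalk`.
#' @param clean_ref_ranges Emit bare range bounds without modifiers.
#' @return Tibble of observation view rows (attributes as in
#'   [build_labs_view_i2b2()]).
#' @export
build_labs_view_pcornet <- function(sts, xw, clean_ref_ranges = FALSE) {
  stopifnot(inherits(sts, "source_table_set"), sts$model == "pcornet")
  labs <- sts$tables$LAB_RESULT_CM
  n_input <- nrow(labs)
  resolved <- resolve_pcornet_result_fields(
    labs$RESULT_UNIT, labs$RESULT_QUAL, labs$RAW_RESULT,
    labs$SPECIMEN_DATE, labs$LAB_ORDER_DATE)
  view <- tibble(
    obs_identifier = labs$LAB_RESULT_CM_ID,
    obs_subject_reference = paste0("Patient/", labs$PATID),
    obs_context_reference = paste0("Encounter/", labs$ENCOUNTERID),
    obs_category_syst = fhir_systems$obs_category,
    obs_category_code = "laboratory",
    obs_category_display = "Laboratory",
    obs_code_coding_syst = fhir_systems$loinc,
    obs_code_coding_code = labs$LAB_LOINC,
    obs_code_coding_display = NA_character_,
    obs_valuequantity_value = labs$RESULT_NUM,
    obs_valuequantity_comparator =
      lookup_codes(xw, "LAB_RESULT_CM", "RESULT_MODIFIER",
                   labs$RESULT_MODIFIER),
    obs_valuequantity_code = resolved$unit,
    obs_valuecodeableconcept_syst = NA_character_,
    obs_valuecodeableconcept_code = NA_character_,
    obs_valuestring = resolved$valuestring,
    obs_issued = labs$RESULT_DATE,
    obs_effectivedatetime = resolved$effective,
    obs_refrange_low = format_pcornet_ref_range(
      labs$NORM_MODIFIER_LOW, labs$NORM_RANGE_LOW, clean = clean_ref_ranges),
    obs_refrange_high = format_pcornet_ref_range(
      labs$NORM_MODIFIER_HIGH, labs$NORM_RANGE_HIGH, clean = clean_ref_ranges),
    obs_interpretation_code =
      lookup_codes(xw, "LAB_RESULT_CM", "ABN_IND", labs$ABN_IND),
    obs_interpretation_syst = NA_character_
  )
  view$obs_interpretation_syst[!is.na(view$obs_interpretation_code)] <-
    fhir_systems$obs_interpretation
  finish_view(view, "obs_identifier", n_input)
}
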