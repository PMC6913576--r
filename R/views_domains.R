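# The seven non-labs views. Column rosters follow the DOMAINPREFIX_FIELD
# convention of the labs view; the full view contract is documented in the
# methods vignette. All views share the null-on-unmappable rule: a crosswalk
# miss leaves the field empty, it never aborts the run.

#' Build the patient view
#'
#' Demographics translated through the crosswalk: gender, race and ethnicity
#' codes are emitted only when a crosswalk row supplies a FHIR code (the
#' documented lossy mappings — e.g. multiple-race patients — come out empty).
#' The PCORnet DEMOGRAPHIC fields with no FHIR equivalent
#' (SEXUAL_ORIENTATION, GENDER_IDENTITY, BIOBANK_FLAG) are never consumed.
#'
#' @param sts A `source_table_set`.
#' @param xw A `fhir_crosswalk`.
#' @return Tibble of patient view rows.
#' @export
build_patient_view <- function(sts, xw) {
  stopifnot(inherits(sts, "source_table_set"))
  if (sts$model == "i2b2") {
    pd <- sts$tables$PATIENT_DIMENSION
    view <- tibble(
      pat_identifier = pd$PATIENT_NUM,
      pat_gender_code = lookup_codes(xw, "PATIENT_DIMENSION", "SEX_CD",
                                     pd$SEX_CD),
      pat_birthdate = pd$BIRTH_DATE,
      pat_deceased = ifelse(is.na(pd$VITAL_STATUS_CD), NA,
                            pd$VITAL_STATUS_CD == "Y"),
      pat_race_code = lookup_codes(xw, "PATIENT_DIMENSION", "RACE_CD",
                                   pd$RACE_CD),
      pat_race_syst = lookup_systems(xw, "PATIENT_DIMENSION", "RACE_CD",
                                     pd$RACE_CD),
      pat_ethnicity_code = lookup_codes(xw, "PATIENT_DIMENSION",
                                        "ETHNICITY_CD", pd$ETHNICITY_CD),
      pat_ethnicity_syst = lookup_systems(xw, "PATIENT_DIMENSION",
                                          "ETHNICITY_CD", pd$ETHNICITY_CD)
    )
  } else {
    dem <- sts$tables$DEMOGRAPHIC
    view <- tibble(
      pat_identifier = dem$PATID,
      pat_gender_code = lookup_codes(xw, "DEMOGRAPHIC", "SEX", dem$SEX),
      pat_birthdate = dem$BIRTH_DATE,
      pat_deceased = NA,
      pat_race_code = lookup_codes(xw, "DEMOGRAPHIC", "RACE", dem$RACE),
      pat_race_syst = lookup_systems(xw, "DEMOGRAPHIC", "RACE", dem$RACE),
      pat_ethnicity_code = lookup_codes(xw, "DEMOGRAPHIC", "HISPANIC",
                                        dem$HISPANIC),
      pat_ethnicity_syst = lookup_systems(xw, "DEMOGRAPHIC", "HISPANIC",
                                          dem$HISPANIC)
    )
  }
  finish_view(view, "pat_identifier", nrow(view))
}

#' Build the encounter view
#'
#' The encounter class comes from the crosswalk (`INOUT_CD` for i2b2,
#' `ENC_TYPE` for PCORnet); discharge disposition and admitting source
#' (PCORnet only) likewise, with empty values where FHIR has no equivalent.
#'
#' @inheritParams build_patient_view
#' @return Tibble of encounter view rows.
#' @export
build_encounter_view <- function(sts, xw) {
  stopifnot(inherits(sts, "source_table_set"))
  if (sts$model == "i2b2") {
    vd <- sts$tables$VISIT_DIMENSION
    view <- tibble(
      enc_identifier = vd$ENCOUNTER_NUM,
      enc_subject_reference = paste0("Patient/", vd$PATIENT_NUM),
      enc_class_code = lookup_codes(xw, "VISIT_DIMENSION", "INOUT_CD",
                                    vd$INOUT_CD),
      enc_class_syst = lookup_systems(xw, "VISIT_DIMENSION", "INOUT_CD",
                                      vd$INOUT_CD),
      enc_period_start = vd$START_DATE,
      enc_period_end = vd$END_DATE,
      enc_dischargedisposition_code = NA_character_,
      enc_dischargedisposition_syst = NA_character_,
      enc_admitsource_code = NA_character_,
      enc_admitsource_syst = NA_character_
    )
  } else {
    enc <- sts$tables$ENCOUNTER
    view <- tibble(
      enc_identifier = enc$ENCOUNTERID,
      enc_subject_reference = paste0("Patient/", enc$PATID),
      enc_class_code = lookup_codes(xw, "ENCOUNTER", "ENC_TYPE",
                                    enc$ENC_TYPE),
      enc_class_syst = lookup_systems(xw, "ENCOUNTER", "ENC_TYPE",
                                      enc$ENC_TYPE),
      enc_period_start = enc$ADMIT_DATE,
      enc_period_end = enc$DISCHARGE_DATE,
      enc_dischargedisposition_code =
        lookup_codes(xw, "ENCOUNTER", "DISCHARGE_STATUS",
                     enc$DISCHARGE_STATUS),
      enc_dischargedisposition_syst =
        lookup_systems(xw, "ENCOUNTER", "DISCHARGE_STATUS",
                       enc$DISCHARGE_STATUS),
      enc_admitsource_code =
        lookup_codes(xw, "ENCOUNTER", "ADMITTING_SOURCE",
                     enc$ADMITTING_SOURCE),
      enc_admitsource_syst =
        lookup_systems(xw, "ENCOUNTER", "ADMITTING_SOURCE",
                       enc$ADMITTING_SOURCE)
    )
  }
  finish_view(view, "enc_identifier", nrow(view))
}

# shared scaffolding for the three i2b2 fact-based coded-event views
i2b2_coded_view <- function(sts, prefix, system, strip) {
  ofc <- sts$tables$OBSERVATION_FACT
  qualifying <- ofc[!is.na(ofc$CONCEPT_CD) &
                      startsWith(ofc$CONCEPT_CD, prefix), , drop = FALSE]
  n_input <- nrow(qualifying)
  joined <- semi_join(qualifying, sts$tables$VISIT_DIMENSION,
                      by = "ENCOUNTER_NUM")
  n_no_visit <- n_input - nrow(joined)
  joined <- left_join(joined, sts$tables$CONCEPT_DIMENSION, by = "CONCEPT_CD")
  code <- joined$CONCEPT_CD
  if (strip) code <- strip_code_prefix(code)
  list(j = joined, code = code, system = system,
       n_input = n_input, n_no_visit = n_no_visit)
}

#' Build the condition view
#'
#' i2b2 draws diagnosis facts by concept-code prefix (default `"ICD10"`) and
#' keeps the code verbatim unless `strip_prefix`; PCORnet reads the
#' DIAGNOSIS table. Condition codes carry the ICD-10-CM system URI. The
#' PCORnet fields DX_ORIGIN and DX_POA have no FHIR equivalent and are never
#' consumed.
#'
#' @inheritParams build_patient_view
#' @param dx_code_prefix i2b2 concept prefix for diagnoses.
#' @param strip_prefix Drop the code-system prefix from i2b2 codes.
#' @return Tibble of condition view rows.
#' @export
build_condition_view <- function(sts, xw, dx_code_prefix = "ICD10",
                                 strip_prefix = FALSE) {
  stopifnot(inherits(sts, "source_table_set"))
  if (sts$model == "i2b2") {
    q <- i2b2_coded_view(sts, dx_code_prefix, fhir_systems$icd10cm,
                         strip_prefix)
    view <- tibble(
      cond_identifier = build_obs_identifier(
        q$j$PATIENT_NUM, q$j$ENCOUNTER_NUM, q$j$PROVIDER_ID,
        q$j$START_DATE, q$j$CONCEPT_CD, q$j$INSTANCE_NUM),
      cond_subject_reference = paste0("Patient/", q$j$PATIENT_NUM),
      cond_context_reference = paste0("Encounter/", q$j$ENCOUNTER_NUM),
      cond_code_coding_syst = q$system,
      cond_code_coding_code = q$code,
      cond_code_coding_display = q$j$NAME_CHAR,
      cond_onsetdatetime = q$j$START_DATE
    )
    return(finish_view(view, "cond_identifier", q$n_input, q$n_no_visit))
  }
  dx <- sts$tables$DIAGNOSIS
  view <- tibble(
    cond_identifier = dx$DIAGNOSISID,
    cond_subject_reference = paste0("Patient/", dx$PATID),
    cond_context_reference = paste0("Encounter/", dx$ENCOUNTERID),
    cond_code_coding_syst = fhir_systems$icd10cm,
    cond_code_coding_code = dx$DX,
    cond_code_coding_display = NA_character_,
    cond_onsetdatetime = dx$DX_DATE
  )
  finish_view(view, "cond_identifier", nrow(dx))
}

#' Build the procedure view
#'
#' i2b2 procedure facts by prefix (default `"CPT"`); PCORnet PROCEDURES
#' table. PX_SOURCE has no FHIR equivalent and is never consumed.
#'
#' @inheritParams build_condition_view
#' @param px_code_prefix i2b2 concept prefix for procedures.
#' @return Tibble of procedure view rows.
#' @export
build_procedure_view <- function(sts, xw, px_code_prefix = "CPT",
                                 strip_prefix = FALSE) {
  stopifnot(inherits(sts, "source_table_set"))
  if (sts$model == "i2b2") {
    q <- i2b2_coded_view(sts, px_code_prefix, fhir_systems$cpt, strip_prefix)
    view <- tibble(
      proc_identifier = build_obs_identifier(
        q$j$PATIENT_NUM, q$j$ENCOUNTER_NUM, q$j$PROVIDER_ID,
        q$j$START_DATE, q$j$CONCEPT_CD, q$j$INSTANCE_NUM),
      proc_subject_reference = paste0("Patient/", q$j$PATIENT_NUM),
      proc_context_reference = paste0("Encounter/", q$j$ENCOUNTER_NUM),
      proc_code_coding_syst = q$system,
      proc_code_coding_code = q$code,
      proc_code_coding_display = q$j$NAME_CHAR,
      proc_performeddatetime = q$j$START_DATE
    )
    return(finish_view(view, "proc_identifier", q$n_input, q$n_no_visit))
  }
  px <- sts$tables$PROCEDURES
  view <- tibble(
    proc_identifier = px$PROCEDURESID,
    proc_subject_reference = paste0("Patient/", px$PATID),
    proc_context_reference = paste0("Encounter/", px$ENCOUNTERID),
    proc_code_coding_syst = fhir_systems$cpt,
    proc_code_coding_code = px$PX,
    proc_code_coding_display = NA_character_,
    proc_performeddatetime = px$PX_DATE
  )
  finish_view(view, "proc_identifier", nrow(px))
}

#' Build the medication-request view
#'
#' Medication codes carry the RxNorm system URI; i2b2 draws facts by prefix
#' (default `"RXNORM"`), PCORnet reads PRESCRIBING. RX_SOURCE has no FHIR
#' equivalent and is never consumed.
#'
#' @inheritParams build_condition_view
#' @param rx_code_prefix i2b2 concept prefix for medications.
#' @return Tibble of medication-request view rows.
#' @export
build_medrequest_view <- function(sts, xw, rx_code_prefix = "RXNORM",
                                  strip_prefix = FALSE) {
  stopifnot(inherits(sts, "source_table_set"))
  if (sts$model == "i2b2") {
    q <- i2b2_coded_view(sts, rx_code_prefix, fhir_systems$rxnorm,
                         strip_prefix)
    view <- tibble(
      medreq_identifier = build_obs_identifier(
        q$j$PATIENT_NUM, q$j$ENCOUNTER_NUM, q$j$PROVIDER_ID,
        q$j$START_DATE, q$j$CONCEPT_CD, q$j$INSTANCE_NUM),
      medreq_subject_reference = paste0("Patient/", q$j$PATIENT_NUM),
      medreq_context_reference = paste0("Encounter/", q$j$ENCOUNTER_NUM),
      medreq_medication_syst = q$system,
      medreq_medication_code = q$code,
      medreq_medication_display = q$j$NAME_CHAR,
      medreq_authoredon = q$j$START_DATE
    )
    return(finish_view(view, "medreq_identifier", q$n_input, q$n_no_visit))
  }
  rx <- sts$tables$PRESCRIBING
  view <- tibble(
    medreq_identifier = rx$PRESCRIBINGID,
    medreq_subject_reference = paste0("Patient/", rx$PATID),
    medreq_context_reference = paste0("Encounter/", rx$ENCOUNTERID),
    medreq_medication_syst = fhir_systems$rxnorm,
    medreq_medication_code = rx$RXNORM_CUI,
    medreq_medication_display = rx$RAW_RX_MED_NAME,
    medreq_authoredon = rx$RX_ORDER_DATE
  )
  finish_view(view, "medreq_identifier", nrow(rx))
}

#' Build the practitioner view
#' @inheritParams build_patient_view
#' @return Tibble of practitioner view rows.
#' @export
build_practitioner_view <- function(sts, xw) {
  stopifnot(inherits(sts, "source_table_set"))
  if (sts$model == "i2b2") {
    prov <- sts$tables$PROVIDER_DIMENSION
    view <- tibble(
      pract_identifier = prov$PROVIDER_ID,
      pract_name = prov$NAME_CHAR
    )
  } else {
    prov <- sts$tables$PROVIDER
    view <- tibble(
      pract_identifier = prov$PROVIDERID,
      pract_name = prov$RAW_PROVIDER_NAME
    )
  }
  finish_view(view, "pract_identifier", nrow(view))
}

#' Build the vitals observation view
#'
#' Height, weight and smoking status as `vital-signs` observations coded
#' with their standard LOINC codes (8302-2, 29463-7, 72166-2). Smoking
#' status descriptors are translated through the crosswalk into coded
#' values; an unmappable descriptor leaves the value empty. i2b2 draws
#' vitals facts by concept prefix (default `"VITAL"`, concepts `VITAL:HT`,
#' `VITAL:WT`, `VITAL:SMOKING`); PCORnet reads the VITAL table, whose
#' unmappable fields (VITAL_SOURCE, BP_POSITION, TOBACCO, TOBACCO_TYPE) are
#' never consumed.
#'
#' @inheritParams build_patient_view
#' @param vital_code_prefix i2b2 concept prefix for vitals facts.
#' @return Tibble of observation view rows (same roster as the labs view).
#' @export
build_vitals_view <- function(sts, xw, vital_code_prefix = "VITAL") {
  stopifnot(inherits(sts, "source_table_set"))
  blank_obs_row <- function(n) {
    tb <- tibble(.rows = n)
    for (cn in obs_view_cols) {
      tb[[cn]] <- if (cn %in% c("obs_issued", "obs_effectivedatetime")) {
        as.Date(rep(NA, n))
      } else if (cn == "obs_valuequantity_value") {
        rep(NA_real_, n)
      } else rep(NA_character_, n)
    }
    tb$obs_category_syst <- fhir_systems$obs_category
    tb$obs_category_code <- "vital-signs"
    tb$obs_category_display <- "Vital Signs"
    tb$obs_code_coding_syst <- fhir_systems$loinc
    tb
  }
  if (sts$model == "i2b2") {
    ofc <- sts$tables$OBSERVATION_FACT
    pre <- paste0(vital_code_prefix, ":")
    qualifying <- ofc[!is.na(ofc$CONCEPT_CD) &
                        startsWith(ofc$CONCEPT_CD, pre), , drop = FALSE]
    n_input <- nrow(qualifying)
    joined <- semi_join(qualifying, sts$tables$VISIT_DIMENSION,
                        by = "ENCOUNTER_NUM")
    n_no_visit <- n_input - nrow(joined)
    local <- sub(pre, "", joined$CONCEPT_CD, fixed = TRUE)
    view <- blank_obs_row(nrow(joined))
    view$obs_identifier <- build_obs_identifier(
      joined$PATIENT_NUM, joined$ENCOUNTER_NUM, joined$PROVIDER_ID,
      joined$START_DATE, joined$CONCEPT_CD, joined$INSTANCE_NUM)
    view$obs_subject_reference <- paste0("Patient/", joined$PATIENT_NUM)
    view$obs_context_reference <- paste0("Encounter/", joined$ENCOUNTER_NUM)
    view$obs_issued <- joined$START_DATE
    ht <- local == "HT"; wt <- local == "WT"; sm <- local == "SMOKING"
    view$obs_code_coding_code[ht] <- vitals_loinc$height$code
    view$obs_code_coding_display[ht] <- vitals_loinc$height$display
    view$obs_valuequantity_value[ht] <- joined$NVAL_NUM[ht]
    view$obs_valuequantity_code[ht] <- joined$UNITS_CD[ht]
    view$obs_code_coding_code[wt] <- vitals_loinc$weight$code
    view$obs_code_coding_display[wt] <- vitals_loinc$weight$display
    view$obs_valuequantity_value[wt] <- joined$NVAL_NUM[wt]
    view$obs_valuequantity_code[wt] <- joined$UNITS_CD[wt]
    view$obs_code_coding_code[sm] <- vitals_loinc$smoking$code
    view$obs_code_coding_display[sm] <- vitals_loinc$smoking$display
    view$obs_valuecodeableconcept_code[sm] <-
      lookup_codes(xw, "OBSERVATION_FACT", "SMOKING_CD",
                   joined$TVAL_CHAR[sm])
    view$obs_valuecodeableconcept_syst[sm] <-
      lookup_systems(xw, "OBSERVATION_FACT", "SMOKING_CD",
                     joined$TVAL_CHAR[sm])
    # concepts under the vitals prefix that the view contract doesn't know
    known <- ht | wt | sm
    n_unknown <- sum(!known)
    view <- view[known, , drop = FALSE]
    out <- finish_view(view, "obs_identifier", n_input, n_no_visit)
    if (n_unknown > 0L) {
      attr(out, "skipped") <- bind_rows(
        attr(out, "skipped"),
        tibble(reason = "unknown-vitals-concept", n = as.integer(n_unknown)))
    }
    return(out)
  }
  vit <- sts$tables$VITAL
  one <- function(kind, code, display, value, unit, sm_code, sm_syst) {
    keep <- if (kind == "SMOKING") !is.na(sm_code) | !is.na(vit$SMOKING)
            else !is.na(value)
    v <- blank_obs_row(sum(keep))
    v$obs_identifier <- paste0(vit$VITALID[keep], "-", kind)
    v$obs_subject_reference <- paste0("Patient/", vit$PATID[keep])
    v$obs_context_reference <- paste0("Encounter/", vit$ENCOUNTERID[keep])
    v$obs_issued <- vit$MEASURE_DATE[keep]
    v$obs_code_coding_code <- code
    v$obs_code_coding_display <- display
    if (kind != "SMOKING") {
      v$obs_valuequantity_value <- value[keep]
      v$obs_valuequantity_code <- unit
    } else {
      v$obs_valuecodeableconcept_code <- sm_code[keep]
      v$obs_valuecodeableconcept_syst <- sm_syst[keep]
    }
    v
  }
  sm_code <- lookup_codes(xw, "VITAL", "SMOKING", vit$SMOKING)
  sm_syst <- lookup_systems(xw, "VITAL", "SMOKING", vit$SMOKING)
  view <- bind_rows(
    one("HT", vitals_loinc$height$code, vitals_loinc$height$display,
        vit$HT, vitals_loinc$height$unit, NULL, NULL),
    one("WT", vitals_loinc$weight$code, vitals_loinc$weight$display,
        vit$WT, vitals_loinc$weight$unit, NULL, NULL),
    one("SMOKING", vitals_loinc$smoking$code, vitals_loinc$smoking$display,
        NULL, NULL, sm_code, sm_syst)
  )
  finish_view(view, "obs_identifier", nrow(view))
}
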