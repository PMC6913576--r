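# Seeded synthetic cohort generator. One model-agnostic clinical event
# stream is drawn first; render_i2b2() and render_pcornet() then write the
# same events into the two source schemas with model-appropriate encodings
# (comparator flags vs RESULT_MODIFIER codes, missing units vs the "NI"
# sentinel, local demographic tokens vs PCORnet categorical codes). Code
# identifiers come from fixed bundled pools; values are synthetic and not
# clinically validated.

#' Specification for a synthetic cohort
#'
#' @param n_patients Number of patients (>= 1).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param date_start,date_end Calendar window for clinical events.
#' @param events_per_patient Named list of mean event counts per patient:
#'   `encounters`, `labs`, `diagnoses`, `procedures`, `medications`,
#'   `vitals`. Counts are Poisson-drawn per patient; patients without
#'   encounters carry no clinical events.
#' @param edge_case_rates Named list of fractions in `[0, 1]`:
#'   `comparator` (labs carrying a result comparator), `ni_units` (numeric
#'   labs with no unit information), `text_labs` (qualitative text-valued
#'   labs; disjoint from `comparator`), `unmappable_encounter` (encounter
#'   types absent from the starter crosswalks), `multiple_race` (patients
#'   whose race has no FHIR value), `missing_visit` (i2b2-only dangling
#'   encounter links on lab facts).
#' @param n_providers Size of the provider pool.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 200, seed = 42,
                        date_start = "2015-01-01", date_end = "2019-12-31",
                        events_per_patient = list(
                          encounters = 4, labs = 10, diagnoses = 4,
                          procedures = 2, medications = 3, vitals = 3),
                        edge_case_rates = list(
                          comparator = 0.10, ni_units = 0.10,
                          text_labs = 0.10, unmappable_encounter = 0.05,
                          multiple_race = 0.05, missing_visit = 0),
                        n_providers = 10) {
  defaults_ev <- list(encounters = 4, labs = 10, diagnoses = 4,
                      procedures = 2, medications = 3, vitals = 3)
  defaults_rt <- list(comparator = 0.10, ni_units = 0.10, text_labs = 0.10,
                      unmappable_encounter = 0.05, multiple_race = 0.05,
                      missing_visit = 0)
  events_per_patient <- utils::modifyList(defaults_ev, events_per_patient)
  edge_case_rates <- utils::modifyList(defaults_rt, edge_case_rates)
  rates <- unlist(edge_case_rates)
  stopifnot(n_patients >= 1, all(rates >= 0 & rates <= 1),
            edge_case_rates$comparator + edge_case_rates$text_labs <= 1)
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    date_start = as.Date(date_start), date_end = as.Date(date_end),
    events_per_patient = events_per_patient,
    edge_case_rates = edge_case_rates,
    n_providers = as.integer(n_providers)
  ), class = "cohort_spec")
}

sample_dates <- function(n, from, to) {
  from + sample.int(as.integer(to - from) + 1L, n, replace = TRUE) - 1L
}

#' Generate the model-agnostic clinical event stream
#'
#' @param spec A [cohort_spec()].
#' @return An `event_stream`: named list of tibbles (`patients`,
#'   `providers`, `encounters`, `labs`, `diagnoses`, `procedures`,
#'   `medications`, `vitals`). Identical spec and seed give identical
#'   streams.
#' @export
#' @examples
#' stream <- generate_event_stream(cohort_spec(n_patients = 5, seed = 7))
#' nrow(stream$patients)
generate_event_stream <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, generate_event_stream_impl(spec))
}

generate_event_stream_impl <- function(spec) {
  np <- spec$n_patients
  rates <- spec$edge_case_rates
  ev <- spec$events_per_patient

  patients <- tibble(
    patient_id = as.character(1000L + seq_len(np)),
    sex = sample(c("male", "female"), np, replace = TRUE),
    birth_date = sample_dates(np, as.Date("1935-01-01"),
                              as.Date("2010-12-31")),
    race = ifelse(runif(np) < rates$multiple_race, "multiple",
                  sample(c("white", "black", "asian", "aian", "nhpi"), np,
                         replace = TRUE, prob = c(.6, .2, .1, .05, .05))),
    ethnicity = sample(c("hispanic", "nonhispanic"), np, replace = TRUE,
                       prob = c(.15, .85)),
    deceased = runif(np) < 0.03,
    smoking = sample(c("current", "former", "never"), np, replace = TRUE,
                     prob = c(.2, .3, .5))
  )
  providers <- tibble(
    provider_id = paste0("PR", seq_len(spec$n_providers)),
    name = paste("Provider", seq_len(spec$n_providers))
  )

  n_enc <- stats::rpois(np, ev$encounters)
  encounters <- tibble(
    patient_id = rep(patients$patient_id, n_enc)
  )
  ne <- nrow(encounters)
  if (ne > 0) {
    cls <- sample(c("ambulatory", "emergency", "inpatient"), ne,
                  replace = TRUE, prob = c(.7, .2, .1))
    cls[runif(ne) < rates$unmappable_encounter] <- "unmappable"
    start <- sample_dates(ne, spec$date_start, spec$date_end)
    los <- ifelse(cls == "inpatient", sample(1:7, ne, replace = TRUE), 0L)
    encounters <- mutate(encounters,
      encounter_id = as.character(50000L + row_number()),
      provider_id = sample(providers$provider_id, ne, replace = TRUE),
      class = cls,
      start_date = start,
      end_date = start + los,
      discharge_status = ifelse(cls == "inpatient",
        sample(c("HO", "SN", "RH", "AM", "EX"), ne, replace = TRUE,
               prob = c(.7, .12, .1, .05, .03)), NA_character_),
      admitting_source = ifelse(cls == "inpatient",
        sample(c("ED", "AV", "NH", "IP"), ne, replace = TRUE,
               prob = c(.5, .3, .1, .1)), NA_character_)
    )
  } else {
    encounters <- tibble(
      patient_id = character(), encounter_id = character(),
      provider_id = character(), class = character(),
      start_date = as.Date(character()), end_date = as.Date(character()),
      discharge_status = character(), admitting_source = character()
    )
  }

  # clinical events attach to a random encounter of their patient
  draw_events <- function(mean_n, prefix) {
    has_enc <- patients$patient_id %in% encounters$patient_id
    n_ev <- ifelse(has_enc, stats::rpois(np, mean_n), 0L)
    pat <- rep(patients$patient_id, n_ev)
    if (!length(pat)) {
      return(tibble(event_id = character(), patient_id = character(),
                    encounter_id = character(), provider_id = character(),
                    date = as.Date(character())))
    }
    enc_idx <- map_int(pat, function(p) {
      sample(which(encounters$patient_id == p), 1L)
    })
    tibble(
      event_id = paste0(prefix, sprintf("%06d", seq_along(pat))),
      patient_id = pat,
      encounter_id = encounters$encounter_id[enc_idx],
      provider_id = encounters$provider_id[enc_idx],
      date = encounters$start_date[enc_idx]
    )
  }

  panel <- synthetic_lab_panel()
  labs <- draw_events(ev$labs, "L")
  nl <- nrow(labs)
  if (nl > 0) {
    pick <- sample.int(nrow(panel), nl, replace = TRUE)
    kind_draw <- runif(nl)
    kind <- ifelse(kind_draw < rates$text_labs, "text",
            ifelse(kind_draw < rates$text_labs + rates$comparator,
                   "comparator", "numeric"))
    value <- round(rnorm(nl, panel$mean[pick], panel$sd[pick]), 2)
    comparator <- ifelse(kind == "comparator",
                         sample(c("<", "<=", ">", ">="), nl, replace = TRUE,
                                prob = c(.4, .3, .15, .15)), NA_character_)
    unit <- panel$unit[pick]
    unit[kind != "text" & runif(nl) < rates$ni_units] <- NA_character_
    labs <- mutate(labs,
      loinc = panel$loinc[pick],
      lab_name = panel$name[pick],
      kind = kind,
      value = ifelse(kind == "text", NA_real_, value),
      comparator = comparator,
      unit = ifelse(kind == "text", NA_character_, unit),
      text_result = ifelse(kind == "text",
                           sample(synthetic_text_results(), nl,
                                  replace = TRUE), NA_character_),
      ref_low = as.character(panel$range_low[pick]),
      ref_high = as.character(panel$range_high[pick]),
      abn = dplyr::case_when(
        kind == "text" ~ NA_character_,
        value > panel$range_high[pick] ~ "AH",
        value < panel$range_low[pick] ~ "AL",
        TRUE ~ NA_character_),
      missing_visit = runif(nl) < rates$missing_visit
    )
  } else {
    labs <- mutate(labs, loinc = character(0), lab_name = character(0),
                   kind = character(0), value = numeric(0),
                   comparator = character(0), unit = character(0),
                   text_result = character(0), ref_low = character(0),
                   ref_high = character(0), abn = character(0),
                   missing_visit = logical(0))
  }

  dxp <- synthetic_dx_pool()
  diagnoses <- draw_events(ev$diagnoses, "D")
  if (nrow(diagnoses)) {
    pick <- sample.int(nrow(dxp), nrow(diagnoses), replace = TRUE)
    diagnoses <- mutate(diagnoses, icd10 = dxp$icd10[pick],
                        dx_name = dxp$name[pick])
  } else {
    diagnoses <- mutate(diagnoses, icd10 = character(0),
                        dx_name = character(0))
  }

  pxp <- synthetic_px_pool()
  procedures <- draw_events(ev$procedures, "X")
  if (nrow(procedures)) {
    pick <- sample.int(nrow(pxp), nrow(procedures), replace = TRUE)
    procedures <- mutate(procedures, cpt = pxp$cpt[pick],
                         px_name = pxp$name[pick])
  } else {
    procedures <- mutate(procedures, cpt = character(0),
                         px_name = character(0))
  }

  rxp <- synthetic_rx_pool()
  medications <- draw_events(ev$medications, "M")
  if (nrow(medications)) {
    pick <- sample.int(nrow(rxp), nrow(medications), replace = TRUE)
    medications <- mutate(medications, rxnorm = rxp$rxnorm[pick],
                          rx_name = rxp$name[pick])
  } else {
    medications <- mutate(medications, rxnorm = character(0),
                          rx_name = character(0))
  }

  vitals <- draw_events(ev$vitals, "V")
  nv <- nrow(vitals)
  if (nv) {
    smoking_of <- setNames(patients$smoking, patients$patient_id)
    vitals <- mutate(vitals,
      ht = round(rnorm(nv, 66, 4), 1),
      wt = round(rnorm(nv, 170, 35), 1),
      smoking = unname(smoking_of[.data$patient_id])
    )
  } else {
    vitals <- mutate(vitals, ht = numeric(0), wt = numeric(0),
                     smoking = character(0))
  }

  structure(list(
    patients = patients, providers = providers, encounters = encounters,
    labs = labs, diagnoses = diagnoses, procedures = procedures,
    medications = medications, vitals = vitals
  ), class = "event_stream")
}

# canonical token -> model-local encodings
.i2b2_sex <- c(male = "MALE", female = "FEMALE")
.i2b2_race <- c(white = "WHITE", black = "BLACK", asian = "ASIAN",
                aian = "AMERICAN-INDIAN", nhpi = "PACIFIC-ISLANDER",
                multiple = "MULTIPLE")
.i2b2_ethnicity <- c(hispanic = "HISPANIC", nonhispanic = "NOT-HISPANIC")
.i2b2_class <- c(ambulatory = "OUTPATIENT", emergency = "EMERGENCY",
                 inpatient = "INPATIENT", unmappable = "OBSERVATION")
.i2b2_smoking <- c(current = "CURRENT-SMOKER", former = "FORMER-SMOKER",
                   never = "NEVER-SMOKER")
.i2b2_comparator_flag <- c("<" = "L", "<=" = "LE", ">" = "G", ">=" = "GE")

.pcornet_sex <- c(male = "M", female = "F")
.pcornet_race <- c(white = "05", black = "03", asian = "02", aian = "01",
                   nhpi = "04", multiple = "06")
.pcornet_ethnicity <- c(hispanic = "Y", nonhispanic = "N")
.pcornet_class <- c(ambulatory = "AV", emergency = "ED", inpatient = "IP",
                    unmappable = "EI")
.pcornet_smoking <- c(current = "01", former = "03", never = "04")
.pcornet_modifier <- c("<" = "LT", "<=" = "LE", ">" = "GT", ">=" = "GE")

#' Render an event stream as an i2b2 source table set
#'
#' All clinical events become OBSERVATION_FACT rows with prefixed concept
#' codes (`LOINC:`, `ICD10:`, `CPT:`, `RXNORM:`, `VITAL:`); result
#' comparators become `TVAL_CHAR` flags on numeric facts; labs flagged with
#' the missing-visit edge case get a dangling `ENCOUNTER_NUM` (this edge
#' case exists only in the i2b2 rendering).
#'
#' @param stream An `event_stream`.
#' @return An i2b2 `source_table_set`.
#' @export
render_i2b2 <- function(stream) {
  stopifnot(inherits(stream, "event_stream"))
  p <- stream$patients
  patient_dim <- tibble(
    PATIENT_NUM = p$patient_id,
    SEX_CD = unname(.i2b2_sex[p$sex]),
    BIRTH_DATE = p$birth_date,
    RACE_CD = unname(.i2b2_race[p$race]),
    ETHNICITY_CD = unname(.i2b2_ethnicity[p$ethnicity]),
    VITAL_STATUS_CD = ifelse(p$deceased, "Y", "N"),
    DEATH_DATE = as.Date(NA)
  )
  e <- stream$encounters
  visit_dim <- tibble(
    ENCOUNTER_NUM = e$encounter_id,
    PATIENT_NUM = e$patient_id,
    INOUT_CD = unname(.i2b2_class[e$class]),
    START_DATE = e$start_date,
    END_DATE = e$end_date
  )
  provider_dim <- tibble(
    PROVIDER_ID = stream$providers$provider_id,
    NAME_CHAR = stream$providers$name
  )
  l <- stream$labs
  fact_labs <- tibble(
    PATIENT_NUM = l$patient_id,
    ENCOUNTER_NUM = ifelse(l$missing_visit, paste0("9", l$event_id),
                           l$encounter_id),
    PROVIDER_ID = l$provider_id,
    START_DATE = l$date,
    CONCEPT_CD = paste0("LOINC:", l$loinc),
    VALTYPE_CD = ifelse(l$kind == "text", "T", "N"),
    TVAL_CHAR = ifelse(l$kind == "text", l$text_result,
                       dplyr::coalesce(
                         unname(.i2b2_comparator_flag[l$comparator]), "E")),
    NVAL_NUM = l$value,
    UNITS_CD = l$unit
  )
  d <- stream$diagnoses
  fact_dx <- tibble(
    PATIENT_NUM = d$patient_id, ENCOUNTER_NUM = d$encounter_id,
    PROVIDER_ID = d$provider_id, START_DATE = d$date,
    CONCEPT_CD = paste0("ICD10:", d$icd10),
    VALTYPE_CD = NA_character_, TVAL_CHAR = NA_character_,
    NVAL_NUM = NA_real_, UNITS_CD = NA_character_
  )
  x <- stream$procedures
  fact_px <- tibble(
    PATIENT_NUM = x$patient_id, ENCOUNTER_NUM = x$encounter_id,
    PROVIDER_ID = x$provider_id, START_DATE = x$date,
    CONCEPT_CD = paste0("CPT:", x$cpt),
    VALTYPE_CD = NA_character_, TVAL_CHAR = NA_character_,
    NVAL_NUM = NA_real_, UNITS_CD = NA_character_
  )
  m <- stream$medications
  fact_rx <- tibble(
    PATIENT_NUM = m$patient_id, ENCOUNTER_NUM = m$encounter_id,
    PROVIDER_ID = m$provider_id, START_DATE = m$date,
    CONCEPT_CD = paste0("RXNORM:", m$rxnorm),
    VALTYPE_CD = NA_character_, TVAL_CHAR = NA_character_,
    NVAL_NUM = NA_real_, UNITS_CD = NA_character_
  )
  v <- stream$vitals
  fact_vitals <- bind_rows(
    tibble(PATIENT_NUM = v$patient_id, ENCOUNTER_NUM = v$encounter_id,
           PROVIDER_ID = v$provider_id, START_DATE = v$date,
           CONCEPT_CD = "VITAL:HT", VALTYPE_CD = "N",
           TVAL_CHAR = "E", NVAL_NUM = v$ht, UNITS_CD = "in"),
    tibble(PATIENT_NUM = v$patient_id, ENCOUNTER_NUM = v$encounter_id,
           PROVIDER_ID = v$provider_id, START_DATE = v$date,
           CONCEPT_CD = "VITAL:WT", VALTYPE_CD = "N",
           TVAL_CHAR = "E", NVAL_NUM = v$wt, UNITS_CD = "lb"),
    tibble(PATIENT_NUM = v$patient_id, ENCOUNTER_NUM = v$encounter_id,
           PROVIDER_ID = v$provider_id, START_DATE = v$date,
           CONCEPT_CD = "VITAL:SMOKING", VALTYPE_CD = "T",
           TVAL_CHAR = unname(.i2b2_smoking[v$smoking]),
           NVAL_NUM = NA_real_, UNITS_CD = NA_character_)
  )
  facts <- bind_rows(fact_labs, fact_dx, fact_px, fact_rx, fact_vitals)
  facts <- facts |>
    group_by(.data$PATIENT_NUM, .data$ENCOUNTER_NUM, .data$PROVIDER_ID,
             .data$START_DATE, .data$CONCEPT_CD) |>
    mutate(INSTANCE_NUM = row_number()) |>
    ungroup() |>
    select(all_of(names(.i2b2_schema$OBSERVATION_FACT$cols)))
  concept_dim <- distinct(bind_rows(
    tibble(CONCEPT_CD = paste0("LOINC:", synthetic_lab_panel()$loinc),
           NAME_CHAR = synthetic_lab_panel()$name),
    tibble(CONCEPT_CD = paste0("ICD10:", synthetic_dx_pool()$icd10),
           NAME_CHAR = synthetic_dx_pool()$name),
    tibble(CONCEPT_CD = paste0("CPT:", synthetic_px_pool()$cpt),
           NAME_CHAR = synthetic_px_pool()$name),
    tibble(CONCEPT_CD = paste0("RXNORM:", synthetic_rx_pool()$rxnorm),
           NAME_CHAR = synthetic_rx_pool()$name),
    tibble(CONCEPT_CD = c("VITAL:HT", "VITAL:WT", "VITAL:SMOKING"),
           NAME_CHAR = c("Body height", "Body weight",
                         "Tobacco smoking status"))
  ))
  suppressWarnings(new_source_table_set("i2b2", list(
    OBSERVATION_FACT = facts,
    PATIENT_DIMENSION = patient_dim,
    VISIT_DIMENSION = visit_dim,
    CONCEPT_DIMENSION = concept_dim,
    PROVIDER_DIMENSION = provider_dim
  )))
}

#' Render an event stream as a PCORnet source table set
#'
#' The same events as [render_i2b2()] in the PCORnet CDM v4.1 schema:
#' comparators as `RESULT_MODIFIER` codes, missing units as the `"NI"`
#' sentinel, demographics and smoking as PCORnet categorical codes. Fields
#' with no FHIR equivalent are populated with plausible fillers so that the
#' transform demonstrably ignores them. The missing-visit edge case is not
#' rendered here: PCORnet enforces encounter referential integrity.
#'
#' @param stream An `event_stream`.
#' @return A PCORnet `source_table_set`.
#' @export
render_pcornet <- function(stream) {
  stopifnot(inherits(stream, "event_stream"))
  p <- stream$patients
  demographic <- tibble(
    PATID = p$patient_id,
    BIRTH_DATE = p$birth_date,
    SEX = unname(.pcornet_sex[p$sex]),
    RACE = unname(.pcornet_race[p$race]),
    HISPANIC = unname(.pcornet_ethnicity[p$ethnicity]),
    SEXUAL_ORIENTATION = "NI",
    GENDER_IDENTITY = "NI",
    BIOBANK_FLAG = "N"
  )
  e <- stream$encounters
  encounter <- tibble(
    ENCOUNTERID = e$encounter_id,
    PATID = e$patient_id,
    ADMIT_DATE = e$start_date,
    DISCHARGE_DATE = e$end_date,
    ENC_TYPE = unname(.pcornet_class[e$class]),
    DISCHARGE_STATUS = e$discharge_status,
    ADMITTING_SOURCE = e$admitting_source,
    PROVIDERID = e$provider_id
  )
  d <- stream$diagnoses
  diagnosis <- tibble(
    DIAGNOSISID = d$event_id, PATID = d$patient_id,
    ENCOUNTERID = d$encounter_id, DX = d$icd10, DX_TYPE = "10",
    DX_DATE = d$date, DX_ORIGIN = "BI", DX_POA = "NI",
    PROVIDERID = d$provider_id
  )
  x <- stream$procedures
  procedures <- tibble(
    PROCEDURESID = x$event_id, PATID = x$patient_id,
    ENCOUNTERID = x$encounter_id, PX = x$cpt, PX_TYPE = "CH",
    PX_DATE = x$date, PX_SOURCE = "BI", PROVIDERID = x$provider_id
  )
  v <- stream$vitals
  vital <- tibble(
    VITALID = v$event_id, PATID = v$patient_id,
    ENCOUNTERID = v$encounter_id, MEASURE_DATE = v$date,
    HT = v$ht, WT = v$wt,
    SMOKING = unname(.pcornet_smoking[v$smoking]),
    VITAL_SOURCE = "HC", BP_POSITION = NA_character_,
    TOBACCO = "NI", TOBACCO_TYPE = "NI"
  )
  l <- stream$labs
  lab <- tibble(
    LAB_RESULT_CM_ID = l$event_id,
    PATID = l$patient_id,
    ENCOUNTERID = l$encounter_id,
    LAB_LOINC = l$loinc,
    RESULT_NUM = l$value,
    RESULT_MODIFIER = ifelse(l$kind == "text", "TX",
                             dplyr::coalesce(
                               unname(.pcornet_modifier[l$comparator]),
                               "EQ")),
    RESULT_UNIT = ifelse(l$kind == "text", "NI",
                         dplyr::coalesce(l$unit, "NI")),
    RESULT_QUAL = ifelse(l$kind == "text", l$text_result, NA_character_),
    RAW_RESULT = NA_character_,
    RESULT_DATE = l$date,
    SPECIMEN_DATE = l$date,
    LAB_ORDER_DATE = l$date,
    NORM_MODIFIER_LOW = "GE",
    NORM_MODIFIER_HIGH = "LE",
    NORM_RANGE_LOW = l$ref_low,
    NORM_RANGE_HIGH = l$ref_high,
    ABN_IND = dplyr::coalesce(l$abn, "NI"),
    RESULT_LOC = "L"
  )
  m <- stream$medications
  prescribing <- tibble(
    PRESCRIBINGID = m$event_id, PATID = m$patient_id,
    ENCOUNTERID = m$encounter_id, RXNORM_CUI = m$rxnorm,
    RX_ORDER_DATE = m$date, RAW_RX_MED_NAME = m$rx_name,
    RX_SOURCE = "OD", RX_PROVIDERID = m$provider_id
  )
  provider <- tibble(
    PROVIDERID = stream$providers$provider_id,
    PROVIDER_SEX = "OT",
    PROVIDER_NPI = paste0("99", sub("^PR", "", stream$providers$provider_id)),
    RAW_PROVIDER_NAME = stream$providers$name
  )
  new_source_table_set("pcornet", list(
    DEMOGRAPHIC = demographic, ENCOUNTER = encounter,
    DIAGNOSIS = diagnosis, PROCEDURES = procedures, VITAL = vital,
    LAB_RESULT_CM = lab, PRESCRIBING = prescribing, PROVIDER = provider
  ))
}

#' Write the canonical event stream as CSVs (for oracle checks)
#'
#' @param stream An `event_stream`.
#' @param dir_path Output directory.
#' @return `dir_path`, invisibly.
#' @export
write_event_stream <- function(stream, dir_path) {
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(stream)) {
    readr::write_csv(stream[[nm]],
                     file.path(dir_path, paste0("events_", nm, ".csv")),
                     na = "", progress = FALSE)
  }
  invisible(dir_path)
}
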