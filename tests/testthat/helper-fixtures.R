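library(dplyr, warn.conflicts = FALSE)
library(purrr, warn.conflicts = FALSE)

# Hand-built micro fixtures used across tests. All constructed in code; the
# seeded generator provides anything larger.

tiny_i2b2_tables <- function() {
  list(
    OBSERVATION_FACT = tibble::tibble(
      PATIENT_NUM  = c("1", "1", "1", "2", "2"),
      ENCOUNTER_NUM = c("10", "10", "99", "11", "11"),
      PROVIDER_ID  = c("P1", "P1", "P1", "P2", "P2"),
      START_DATE   = as.Date(c("2019-01-05", "2019-01-05", "2019-01-06",
                               "2019-02-01", "2019-02-01")),
      CONCEPT_CD   = c("LOINC:2345-7", "LOINC:2345-7", "LOINC:718-7",
                       "ICD10:J45.40", "LOINC:9999-9"),
      INSTANCE_NUM = c(1L, 1L, 1L, 1L, 1L),
      VALTYPE_CD   = c("N", "N", "N", NA, "T"),
      TVAL_CHAR    = c("LE", "LE", "E", NA, "POSITIVE"),
      NVAL_NUM     = c(7.2, 7.2, 13.1, NA, NA),
      UNITS_CD     = c("mg/dL", "mg/dL", "g/dL", NA, NA)
    ),
    PATIENT_DIMENSION = tibble::tibble(
      PATIENT_NUM = c("1", "2"),
      SEX_CD = c("FEMALE", "MALE"),
      BIRTH_DATE = as.Date(c("1980-03-01", "1975-07-12")),
      RACE_CD = c("WHITE", "MULTIPLE"),
      ETHNICITY_CD = c("NOT-HISPANIC", "HISPANIC"),
      VITAL_STATUS_CD = c("N", "N"),
      DEATH_DATE = as.Date(c(NA, NA))
    ),
    VISIT_DIMENSION = tibble::tibble(
      ENCOUNTER_NUM = c("10", "11"),
      PATIENT_NUM = c("1", "2"),
      INOUT_CD = c("INPATIENT", "OUTPATIENT"),
      START_DATE = as.Date(c("2019-01-05", "2019-02-01")),
      END_DATE = as.Date(c("2019-01-08", "2019-02-01"))
    ),
    CONCEPT_DIMENSION = tibble::tibble(
      CONCEPT_CD = c("LOINC:2345-7", "ICD10:J45.40"),
      NAME_CHAR = c("Glucose", "Moderate persistent asthma")
    ),
    PROVIDER_DIMENSION = tibble::tibble(
      PROVIDER_ID = c("P1", "P2"),
      NAME_CHAR = c("Provider One", "Provider Two")
    )
  )
}

tiny_i2b2 <- function() {
  suppressWarnings(new_source_table_set("i2b2", tiny_i2b2_tables()))
}

# minimal PCORnet set with two lab rows exercising the sentinel branches
tiny_pcornet <- function() {
  new_source_table_set("pcornet", list(
    DEMOGRAPHIC = tibble::tibble(
      PATID = c("1", "2"), BIRTH_DATE = as.Date(c("1980-03-01", "1975-07-12")),
      SEX = c("F", "M"), RACE = c("05", "06"), HISPANIC = c("N", "Y"),
      SEXUAL_ORIENTATION = "NI", GENDER_IDENTITY = "NI", BIOBANK_FLAG = "N"),
    ENCOUNTER = tibble::tibble(
      ENCOUNTERID = c("10", "11"), PATID = c("1", "2"),
      ADMIT_DATE = as.Date(c("2019-01-05", "2019-02-01")),
      DISCHARGE_DATE = as.Date(c("2019-01-08", "2019-02-01")),
      ENC_TYPE = c("IP", "EI"), DISCHARGE_STATUS = c("HO", "NI"),
      ADMITTING_SOURCE = c("ED", "NI"), PROVIDERID = c("P1", "P2")),
    DIAGNOSIS = tibble::tibble(
      DIAGNOSISID = "D1", PATID = "2", ENCOUNTERID = "11", DX = "J45.40",
      DX_TYPE = "10", DX_DATE = as.Date("2019-02-01"), DX_ORIGIN = "BI",
      DX_POA = "NI", PROVIDERID = "P2"),
    PROCEDURES = tibble::tibble(
      PROCEDURESID = "X1", PATID = "1", ENCOUNTERID = "10", PX = "99213",
      PX_TYPE = "CH", PX_DATE = as.Date("2019-01-05"), PX_SOURCE = "BI",
      PROVIDERID = "P1"),
    VITAL = tibble::tibble(
      VITALID = "V1", PATID = "1", ENCOUNTERID = "10",
      MEASURE_DATE = as.Date("2019-01-05"), HT = 66.1, WT = 150.2,
      SMOKING = "04", VITAL_SOURCE = "HC", BP_POSITION = NA_character_,
      TOBACCO = "NI", TOBACCO_TYPE = "NI"),
    LAB_RESULT_CM = tibble::tibble(
      LAB_RESULT_CM_ID = c("L1", "L2"),
      PATID = c("1", "2"), ENCOUNTERID = c("10", "11"),
      LAB_LOINC = c("2345-7", "718-7"),
      RESULT_NUM = c(7.2, NA),
      RESULT_MODIFIER = c("LE", "TX"),
      RESULT_UNIT = c("mg/dL", "NI"),
      RESULT_QUAL = c(NA, "POSITIVE"),
      RAW_RESULT = c(NA, NA),
      RESULT_DATE = as.Date(c("2019-01-05", "2019-02-01")),
      SPECIMEN_DATE = as.Date(c("2019-01-05", NA)),
      LAB_ORDER_DATE = as.Date(c("2019-01-04", "2019-01-30")),
      NORM_MODIFIER_LOW = c("GE", NA), NORM_MODIFIER_HIGH = c("LE", NA),
      NORM_RANGE_LOW = c("3.5", NA), NORM_RANGE_HIGH = c("10", NA),
      ABN_IND = c("AH", "NI"), RESULT_LOC = "L"),
    PRESCRIBING = tibble::tibble(
      PRESCRIBINGID = "M1", PATID = "1", ENCOUNTERID = "10",
      RXNORM_CUI = "435", RX_ORDER_DATE = as.Date("2019-01-05"),
      RAW_RX_MED_NAME = "Albuterol", RX_SOURCE = "OD", RX_PROVIDERID = "P1"),
    PROVIDER = tibble::tibble(
      PROVIDERID = c("P1", "P2"), PROVIDER_SEX = "OT",
      PROVIDER_NPI = c("991", "992"),
      RAW_PROVIDER_NAME = c("Provider One", "Provider Two"))
  ))
}

write_crosswalk_file <- function(rows) {
  path <- tempfile(fileext = ".csv")
  writeLines(c("TABLE_CD,COLUMN_CD,LOCAL_IN_CD,FHIR_OUT_CD,FHIR_SYSTEM",
               rows), path)
  path
}

# the three encounter-class rows printed in the source mapping-table excerpt
table2_crosswalk <- function() {
  sys <- "https://hl7.org/fhir/STU3/v3/ActEncounterCode/vs.html"
  write_crosswalk_file(c(
    paste0("VISIT_DIMENSION,INOUT_CD,EMERGENCY,EMER,", sys),
    paste0("VISIT_DIMENSION,INOUT_CD,INPATIENT,IMP,", sys),
    paste0("VISIT_DIMENSION,INOUT_CD,OUTPATIENT,AMB,", sys)
  ))
}

lossless_spec <- function(n_patients = 20, seed = 3) {
  cohort_spec(n_patients = n_patients, seed = seed,
              edge_case_rates = list(unmappable_encounter = 0,
                                     multiple_race = 0, missing_visit = 0))
}
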