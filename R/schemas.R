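# Table schemas for the two supported source models.
#
# Column types: "character", "numeric", "integer", "date". Dates in source
# files are ISO 8601 (YYYY-MM-DD, optionally with a time part which is
# dropped); the internal representation is timezone-naive `Date`.

.i2b2_schema <- list(
  OBSERVATION_FACT = list(
    cols = c(
      PATIENT_NUM = "character", ENCOUNTER_NUM = "character",
      PROVIDER_ID = "character", START_DATE = "date",
      CONCEPT_CD = "character", INSTANCE_NUM = "integer",
      VALTYPE_CD = "character", TVAL_CHAR = "character",
      NVAL_NUM = "numeric", UNITS_CD = "character"
    )
  ),
  PATIENT_DIMENSION = list(
    cols = c(
      PATIENT_NUM = "character", SEX_CD = "character", BIRTH_DATE = "date",
      RACE_CD = "character", ETHNICITY_CD = "character",
      VITAL_STATUS_CD = "character", DEATH_DATE = "date"
    )
  ),
  VISIT_DIMENSION = list(
    cols = c(
      ENCOUNTER_NUM = "character", PATIENT_NUM = "character",
      INOUT_CD = "character", START_DATE = "date", END_DATE = "date"
    )
  ),
  CONCEPT_DIMENSION = list(
    cols = c(CONCEPT_CD = "character", NAME_CHAR = "character")
  ),
  PROVIDER_DIMENSION = list(
    cols = c(PROVIDER_ID = "character", NAME_CHAR = "character")
  )
)

.pcornet_schema <- list(
  DEMOGRAPHIC = list(
    cols = c(
      PATID = "character", BIRTH_DATE = "date", SEX = "character",
      RACE = "character", HISPANIC = "character",
      # Declared but never consumed: no FHIR equivalent.
      SEXUAL_ORIENTATION = "character", GENDER_IDENTITY = "character",
      BIOBANK_FLAG = "character"
    )
  ),
  ENCOUNTER = list(
    cols = c(
      ENCOUNTERID = "character", PATID = "character", ADMIT_DATE = "date",
      DISCHARGE_DATE = "date", ENC_TYPE = "character",
      DISCHARGE_STATUS = "character", ADMITTING_SOURCE = "character",
      PROVIDERID = "character"
    )
  ),
  DIAGNOSIS = list(
    cols = c(
      DIAGNOSISID = "character", PATID = "character",
      ENCOUNTERID = "character", DX = "character", DX_TYPE = "character",
      DX_DATE = "date", DX_ORIGIN = "character", DX_POA = "character",
      PROVIDERID = "character"
    )
  ),
  PROCEDURES = list(
    cols = c(
      PROCEDURESID = "character", PATID = "character",
      ENCOUNTERID = "character", PX = "character", PX_TYPE = "character",
      PX_DATE = "date", PX_SOURCE = "character", PROVIDERID = "character"
    )
  ),
  VITAL = list(
    cols = c(
      VITALID = "character", PATID = "character", ENCOUNTERID = "character",
      MEASURE_DATE = "date", HT = "numeric", WT = "numeric",
      SMOKING = "character", VITAL_SOURCE = "character",
      BP_POSITION = "character", TOBACCO = "character",
      TOBACCO_TYPE = "character"
    )
  ),
  LAB_RESULT_CM = list(
    cols = c(
      LAB_RESULT_CM_ID = "character", PATID = "character",
      ENCOUNTERID = "character", LAB_LOINC = "character",
      RESULT_NUM = "numeric", RESULT_MODIFIER = "character",
      RESULT_UNIT = "character", RESULT_QUAL = "character",
      RAW_RESULT = "character", RESULT_DATE = "date",
      SPECIMEN_DATE = "date", LAB_ORDER_DATE = "date",
      NORM_MODIFIER_LOW = "character", NORM_MODIFIER_HIGH = "character",
      NORM_RANGE_LOW = "character", NORM_RANGE_HIGH = "character",
      ABN_IND = "character", RESULT_LOC = "character"
    )
  ),
  PRESCRIBING = list(
    cols = c(
      PRESCRIBINGID = "character", PATID = "character",
      ENCOUNTERID = "character", RXNORM_CUI = "character",
      RX_ORDER_DATE = "date", RAW_RX_MED_NAME = "character",
      RX_SOURCE = "character", RX_PROVIDERID = "character"
    )
  ),
  PROVIDER = list(
    cols = c(
      PROVIDERID = "character", PROVIDER_SEX = "character",
      PROVIDER_NPI = "character", RAW_PROVIDER_NAME = "character"
    )
  )
)

#' Table schema for a source model
#'
#' Returns the declared column roster (name -> type) for every table of one
#' of the two supported common data models.
#'
#' @param model `"i2b2"` or `"pcornet"`.
#' @return A named list, one entry per table, each holding a named character
#'   vector of column types.
#' @export
#' @examples
#' names(cdm_schema("i2b2"))
cdm_schema <- function(model) {
  model <- match.arg(model, c("i2b2", "pcornet"))
  if (model == "i2b2") .i2b2_schema else .pcornet_schema
}

# Column id used as the patient key per table.
.patient_key <- function(model, table) {
  if (model == "i2b2") "PATIENT_NUM" else "PATID"
}
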