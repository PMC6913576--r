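# Fixed code pools for the synthetic cohort generator. The code identifiers
# are real LOINC / ICD-10-CM / RxNorm / CPT tokens so that prefix filters and
# system URIs behave as they would on real extracts, but the value
# distributions attached to them are synthetic and not clinically validated.

#' Synthetic lab panel (LOINC)
#'
#' @return Tibble with `loinc`, `name`, `unit`, `mean`, `sd`, `range_low`,
#'   `range_high` used by [generate_event_stream()] to draw lab values.
#' @export
synthetic_lab_panel <- function() {
  tibble::tribble(
    ~loinc,    ~name,                          ~unit,     ~mean,  ~sd,   ~range_low, ~range_high,
    "2345-7",  "Glucose [Mass/Vol]",           "mg/dL",   95,     18,    70,   110,
    "718-7",   "Hemoglobin [Mass/Vol]",        "g/dL",    13.8,   1.6,   12,   17.5,
    "2160-0",  "Creatinine [Mass/Vol]",        "mg/dL",   1.0,    0.3,   0.6,  1.3,
    "3094-0",  "Urea nitrogen [Mass/Vol]",     "mg/dL",   15,     5,     7,    20,
    "2823-3",  "Potassium [Moles/Vol]",        "mmol/L",  4.2,    0.4,   3.5,  5.1,
    "2951-2",  "Sodium [Moles/Vol]",           "mmol/L",  140,    2.5,   136,  145,
    "17861-6", "Calcium [Mass/Vol]",           "mg/dL",   9.4,    0.5,   8.6,  10.2,
    "2093-3",  "Cholesterol [Mass/Vol]",       "mg/dL",   190,    35,    125,  200,
    "2571-8",  "Triglyceride [Mass/Vol]",      "mg/dL",   130,    60,    50,   150,
    "2085-9",  "HDL Cholesterol",              "mg/dL",   52,     14,    40,   90,
    "13457-7", "LDL Cholesterol (calc)",       "mg/dL",   110,    30,    50,   130,
    "6690-2",  "Leukocytes [#/Vol]",           "10*3/uL", 7.2,    2.0,   4.5,  11,
    "777-3",   "Platelets [#/Vol]",            "10*3/uL", 250,    60,    150,  400,
    "4548-4",  "Hemoglobin A1c",               "%",       5.9,    1.1,   4.0,  5.6,
    "1742-6",  "ALT [Enz/Vol]",                "U/L",     28,     14,    7,    55,
    "1920-8",  "AST [Enz/Vol]",                "U/L",     26,     11,    8,    48,
    "6768-6",  "Alkaline phosphatase",         "U/L",     80,     25,    40,   129,
    "1975-2",  "Bilirubin total",              "mg/dL",   0.7,    0.3,   0.1,  1.2,
    "2885-2",  "Protein total",                "g/dL",    7.0,    0.5,   6.0,  8.3,
    "1751-7",  "Albumin [Mass/Vol]",           "g/dL",    4.3,    0.4,   3.5,  5.0,
    "33914-3", "eGFR",                         "mL/min",  85,     20,    60,   120,
    "2028-9",  "Carbon dioxide",               "mmol/L",  25,     2.5,   22,   29,
    "2075-0",  "Chloride [Moles/Vol]",         "mmol/L",  102,    3,     98,   107,
    "789-8",   "Erythrocytes [#/Vol]",         "10*6/uL", 4.8,    0.5,   4.2,  5.9,
    "4544-3",  "Hematocrit",                   "%",       41,     4.5,   36,   50,
    "30522-7", "CRP high sensitivity",         "mg/L",    2.5,    2.0,   0,    3,
    "2276-4",  "Ferritin [Mass/Vol]",          "ng/mL",   120,    80,    20,   250,
    "2132-9",  "Vitamin B12",                  "pg/mL",   480,    180,   200,  900,
    "14682-9", "Creatinine [Moles/Vol]",       "umol/L",  88,     25,    53,   115,
    "2532-0",  "Lactate dehydrogenase",        "U/L",     180,    45,    120,  250
  )
}

#' Synthetic qualitative lab results
#' @return Character vector of text results used for text-valued labs.
#' @export
synthetic_text_results <- function() {
  c("POSITIVE", "NEGATIVE", "TRACE", "DETECTED", "NOT DETECTED", "CLOUDY",
    "CLEAR", "YELLOW")
}

#' Synthetic diagnosis pool (ICD-10-CM)
#' @return Tibble with `icd10`, `name`.
#' @export
synthetic_dx_pool <- function() {
  tibble::tribble(
    ~icd10,     ~name,
    "J45.40",   "Moderate persistent asthma, uncomplicated",
    "J45.50",   "Severe persistent asthma, uncomplicated",
    "E11.9",    "Type 2 diabetes mellitus without complications",
    "I10",      "Essential (primary) hypertension",
    "E78.5",    "Hyperlipidemia, unspecified",
    "J44.9",    "Chronic obstructive pulmonary disease, unspecified",
    "N39.0",    "Urinary tract infection, site not specified",
    "K21.9",    "Gastro-esophageal reflux disease without esophagitis",
    "F32.9",    "Major depressive disorder, single episode, unspecified",
    "M54.5",    "Low back pain",
    "E03.9",    "Hypothyroidism, unspecified",
    "I25.10",   "Atherosclerotic heart disease without angina",
    "J06.9",    "Acute upper respiratory infection, unspecified",
    "B34.9",    "Viral infection, unspecified",
    "R05",      "Cough",
    "R50.9",    "Fever, unspecified",
    "J02.9",    "Acute pharyngitis, unspecified",
    "H66.90",   "Otitis media, unspecified",
    "L30.9",    "Dermatitis, unspecified",
    "K59.00",   "Constipation, unspecified",
    "G43.909",  "Migraine, unspecified",
    "F41.9",    "Anxiety disorder, unspecified",
    "M25.50",   "Pain in unspecified joint",
    "R10.9",    "Unspecified abdominal pain",
    "D64.9",    "Anemia, unspecified",
    "E55.9",    "Vitamin D deficiency, unspecified",
    "Z23",      "Encounter for immunization",
    "J30.9",    "Allergic rhinitis, unspecified",
    "N18.3",    "Chronic kidney disease, stage 3",
    "E66.9",    "Obesity, unspecified"
  )
}

#' Synthetic medication pool (RxNorm CUIs)
#' @return Tibble with `rxnorm`, `name`.
#' @export
synthetic_rx_pool <- function() {
  tibble::tribble(
    ~rxnorm,   ~name,
    "435",     "Albuterol",
    "746763",  "Albuterol 0.09 MG/ACTUAT inhaler",
    "860975",  "Metformin hydrochloride 500 MG",
    "197361",  "Amlodipine 5 MG oral tablet",
    "29046",   "Lisinopril",
    "83367",   "Atorvastatin",
    "36567",   "Simvastatin",
    "10582",   "Levothyroxine",
    "7646",    "Omeprazole",
    "6809",    "Metformin",
    "1191",    "Aspirin",
    "5640",    "Ibuprofen",
    "161",     "Acetaminophen",
    "723",     "Amoxicillin",
    "2670",    "Codeine",
    "3640",    "Doxycycline",
    "4053",    "Montelukast",
    "41126",   "Fluticasone",
    "8640",    "Prednisone",
    "6918",    "Sertraline"
  )
}

#' Synthetic procedure pool (CPT)
#' @return Tibble with `cpt`, `name`.
#' @export
synthetic_px_pool <- function() {
  tibble::tribble(
    ~cpt,     ~name,
    "99213",  "Office visit, established patient, low complexity",
    "99214",  "Office visit, established patient, moderate complexity",
    "99203",  "Office visit, new patient, low complexity",
    "99285",  "Emergency department visit, high severity",
    "93000",  "Electrocardiogram, complete",
    "71046",  "Chest X-ray, 2 views",
    "80053",  "Comprehensive metabolic panel",
    "85025",  "Complete blood count with differential",
    "36415",  "Collection of venous blood by venipuncture",
    "90471",  "Immunization administration"
  )
}

# Coding-system URIs used by the views and the emitter.
fhir_systems <- list(
  loinc = "http://loinc.org",
  icd10cm = "http://hl7.org/fhir/sid/icd-10-cm",
  rxnorm = "http://www.nlm.nih.gov/research/umls/rxnorm",
  cpt = "http://www.ama-assn.org/go/cpt",
  obs_category = "http://hl7.org/fhir/ValueSet/observation-category",
  obs_interpretation = "http://hl7.org/fhir/ValueSet/observation-interpretation"
)

# Fixed LOINC codes used by the vitals view for the structural vitals.
vitals_loinc <- list(
  height = list(code = "8302-2", display = "Body height", unit = "in"),
  weight = list(code = "29463-7", display = "Body weight", unit = "lb"),
  smoking = list(code = "72166-2", display = "Tobacco smoking status")
)
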