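# The seeded generator and its two renderings.

test_that("generation is deterministic given the seed", {
  spec <- cohort_spec(n_patients = 15, seed = 101)
  expect_identical(generate_event_stream(spec), generate_event_stream(spec))
  other <- generate_event_stream(cohort_spec(n_patients = 15, seed = 102))
  expect_false(identical(generate_event_stream(spec), other))
})

test_that("a patient with no events yields an empty clinical stream", {
  stream <- generate_event_stream(cohort_spec(
    n_patients = 1, seed = 1,
    events_per_patient = list(encounters = 0, labs = 0, diagnoses = 0,
                              procedures = 0, medications = 0, vitals = 0)))
  expect_identical(nrow(stream$patients), 1L)
  expect_identical(nrow(stream$encounters), 0L)
  expect_identical(nrow(stream$labs), 0L)
})

test_that("edge-case fractions land within two points of the spec", {
  stream <- generate_event_stream(cohort_spec(
    n_patients = 500, seed = 7,
    events_per_patient = list(labs = 10),
    edge_case_rates = list(comparator = 0.2)))
  expect_gte(nrow(stream$labs), 1000)
  frac <- mean(!is.na(stream$labs$comparator))
  expect_gte(frac, 0.18); expect_lte(frac, 0.22)
  frac_text <- mean(stream$labs$kind == "text")
  expect_gte(frac_text, 0.08); expect_lte(frac_text, 0.12)
})

test_that("both renderings carry the same event content", {
  stream <- generate_event_stream(cohort_spec(
    n_patients = 1, seed = 4,
    events_per_patient = list(encounters = 1, labs = 1, diagnoses = 0,
                              procedures = 0, medications = 0, vitals = 0),
    edge_case_rates = list(comparator = 0, ni_units = 0, text_labs = 0)))
  expect_identical(nrow(stream$labs), 1L)
  i2 <- render_i2b2(stream)
  pc <- render_pcornet(stream)
  fact <- i2$tables$OBSERVATION_FACT[
    startsWith(i2$tables$OBSERVATION_FACT$CONCEPT_CD, "LOINC"), ]
  lab <- pc$tables$LAB_RESULT_CM
  expect_identical(nrow(fact), 1L)
  expect_identical(nrow(lab), 1L)
  expect_identical(fact$PATIENT_NUM, lab$PATID)
  expect_identical(sub("^LOINC:", "", fact$CONCEPT_CD), lab$LAB_LOINC)
  expect_identical(fact$NVAL_NUM, lab$RESULT_NUM)
  expect_identical(fact$UNITS_CD, lab$RESULT_UNIT)
  expect_identical(fact$START_DATE, lab$RESULT_DATE)
})

test_that("comparator events round-trip to the same FHIR comparator", {
  stream <- generate_event_stream(cohort_spec(
    n_patients = 5, seed = 6,
    edge_case_rates = list(comparator = 1, text_labs = 0)))
  i2 <- render_i2b2(stream); pc <- render_pcornet(stream)
  expect_setequal(unique(i2$tables$OBSERVATION_FACT$TVAL_CHAR[
    startsWith(i2$tables$OBSERVATION_FACT$CONCEPT_CD, "LOINC")]),
    intersect(c("L", "LE", "G", "GE"),
              i2$tables$OBSERVATION_FACT$TVAL_CHAR))
  vi <- build_labs_view_i2b2(i2, strip_prefix = TRUE)
  vp <- build_labs_view_pcornet(
    pc, load_crosswalk(starter_crosswalk_path("pcornet")))
  key <- function(v) arrange(
    tibble::tibble(s = v$obs_subject_reference, c = v$obs_code_coding_code,
                   x = v$obs_valuequantity_value,
                   cm = v$obs_valuequantity_comparator),
    s, c, x, cm)
  expect_identical(key(vi), key(vp))
  expect_true(all(!is.na(vi$obs_valuequantity_comparator)))
})

test_that("unmappable encounter types are absent from the starter crosswalks", {
  stream <- generate_event_stream(cohort_spec(
    n_patients = 30, seed = 8,
    edge_case_rates = list(unmappable_encounter = 1)))
  i2 <- render_i2b2(stream); pc <- render_pcornet(stream)
  xw_i <- load_crosswalk(starter_crosswalk_path("i2b2"))
  xw_p <- load_crosswalk(starter_crosswalk_path("pcornet"))
  for (cd in unique(i2$tables$VISIT_DIMENSION$INOUT_CD)) {
    expect_null(lookup_code(xw_i, "VISIT_DIMENSION", "INOUT_CD", cd))
  }
  for (cd in unique(pc$tables$ENCOUNTER$ENC_TYPE)) {
    expect_null(lookup_code(xw_p, "ENCOUNTER", "ENC_TYPE", cd))
  }
})

test_that("missing visit links are rendered only in i2b2", {
  stream <- generate_event_stream(cohort_spec(
    n_patients = 20, seed = 9,
    edge_case_rates = list(missing_visit = 0.5)))
  expect_gt(sum(stream$labs$missing_visit), 0)
  i2 <- render_i2b2(stream)
  # revalidating the rendered tables surfaces the dangling links as a warning
  expect_warning(new_source_table_set("i2b2", i2$tables),
                 "no VISIT_DIMENSION row")
  pc <- render_pcornet(stream)
  dangling <- setdiff(i2$tables$OBSERVATION_FACT$ENCOUNTER_NUM,
                      i2$tables$VISIT_DIMENSION$ENCOUNTER_NUM)
  expect_identical(length(dangling), sum(stream$labs$missing_visit))
  expect_true(all(pc$tables$LAB_RESULT_CM$ENCOUNTERID %in%
                    pc$tables$ENCOUNTER$ENCOUNTERID))
})

test_that("full-pipeline outputs from both renderings agree tuple-for-tuple", {
  stream <- generate_event_stream(cohort_spec(n_patients = 12, seed = 10))
  xw_i <- load_crosswalk(starter_crosswalk_path("i2b2"))
  xw_p <- load_crosswalk(starter_crosswalk_path("pcornet"))
  d_i <- withr::local_tempdir(); d_p <- withr::local_tempdir()
  transform_source(render_i2b2(stream), xw_i, d_i, strip_prefix = TRUE)
  transform_source(render_pcornet(stream), xw_p, d_p)
  t_i <- fhir_equivalence_tuples(read_fhir_ndjson(d_i))
  t_p <- fhir_equivalence_tuples(read_fhir_ndjson(d_p))
  expect_identical(names(t_i), names(t_p))
  for (nm in names(t_i)) expect_equal(t_i[[nm]], t_p[[nm]], info = nm)
})
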