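# View rows -> STU3 resources -> serialized files.

obs_row <- function(...) {
  defaults <- list(
    obs_identifier = "L1", obs_subject_reference = "Patient/123",
    obs_context_reference = "Encounter/9",
    obs_category_syst = "http://hl7.org/fhir/ValueSet/observation-category",
    obs_category_code = "laboratory", obs_category_display = "Laboratory",
    obs_code_coding_syst = "http://loinc.org",
    obs_code_coding_code = "2345-7", obs_code_coding_display = "Glucose",
    obs_valuequantity_value = 7.2, obs_valuequantity_comparator = "<",
    obs_valuequantity_code = "mg/dL",
    obs_valuecodeableconcept_syst = NA, obs_valuecodeableconcept_code = NA,
    obs_valuestring = NA, obs_issued = "2019-01-05",
    obs_effectivedatetime = NA, obs_refrange_low = NA,
    obs_refrange_high = NA, obs_interpretation_code = NA,
    obs_interpretation_syst = NA)
  utils::modifyList(defaults, list(...))
}

test_that("numeric results become a valueQuantity with comparator and unit", {
  res <- emit_observation(obs_row())
  expect_identical(res$valueQuantity,
                   list(value = 7.2, comparator = "<", unit = "mg/dL"))
  expect_identical(res$subject$reference, "Patient/123")
  expect_identical(res$status, "final")
  expect_identical(res$issued, "2019-01-05T00:00:00Z")
  expect_null(res$valueString)
  expect_length(validate_stu3(res), 0)
})

test_that("text results become valueString with no valueQuantity", {
  res <- emit_observation(obs_row(
    obs_valuequantity_value = NA, obs_valuequantity_comparator = NA,
    obs_valuequantity_code = NA, obs_valuestring = "POSITIVE"))
  expect_identical(res$valueString, "POSITIVE")
  expect_null(res$valueQuantity)
  expect_length(validate_stu3(res), 0)
})

test_that("absent source fields produce absent elements, never nulls", {
  res <- emit_observation(obs_row(
    obs_valuequantity_comparator = NA, obs_code_coding_display = NA,
    obs_context_reference = NA))
  expect_false("comparator" %in% names(res$valueQuantity))
  expect_false("display" %in% names(res$code$coding[[1]]))
  expect_false("context" %in% names(res))
  has_null <- function(x) {
    if (!is.list(x)) return(length(x) == 1 && is.na(x))
    any(vapply(x, has_null, logical(1)))
  }
  expect_false(has_null(unclass(res)))
})

test_that("reference ranges serialize as text", {
  res <- emit_observation(obs_row(obs_refrange_low = "GE 3.5",
                                  obs_refrange_high = "10"))
  expect_identical(res$referenceRange[[1]]$text, "GE 3.5 - 10")
  expect_length(validate_stu3(res), 0)
})

test_that("illegal id characters are sanitized consistently", {
  raw <- "123-456-P9-05-JAN-2019-LOINC:2345-7-1"
  expect_identical(sanitize_fhir_id(raw),
                   "123-456-P9-05-JAN-2019-LOINC.2345-7-1")
  long <- strrep("x:", 60)
  sid <- sanitize_fhir_id(long)
  expect_true(nchar(sid) <= 64)
  expect_true(grepl("^[A-Za-z0-9.-]+$", sid))
  # distinct long ids stay distinct
  expect_false(sanitize_fhir_id(paste0(long, "a")) ==
                 sanitize_fhir_id(paste0(long, "b")))
  res <- emit_observation(obs_row(obs_identifier = raw))
  expect_identical(res$id, sanitize_fhir_id(raw))
})

test_that("emit_domain conserves well-formed rows and orders by id", {
  view <- build_labs_view_pcornet(
    tiny_pcornet(), load_crosswalk(starter_crosswalk_path("pcornet")))
  res <- emit_domain(view, "observation")
  expect_length(res, nrow(view))
  expect_identical(map_chr(res, "id"), sort(map_chr(res, "id")))
  expect_length(emit_domain(view[0, ], "observation"), 0)
  # a row without a subject is skipped and tallied
  broken <- view
  broken$obs_subject_reference[1] <- NA
  res2 <- emit_domain(broken, "observation")
  expect_length(res2, nrow(view) - 1L)
  expect_identical(attr(res2, "skipped"), 1L)
})

test_that("NDJSON serialization is conservative and deterministic", {
  stream <- generate_event_stream(cohort_spec(n_patients = 5, seed = 23))
  sts <- render_pcornet(stream)
  xw <- load_crosswalk(starter_crosswalk_path("pcornet"))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- transform_source(sts, xw, d1)
  m2 <- transform_source(sts, xw, d2)
  labs_lines <- readLines(file.path(d1, "observation_labs.ndjson"))
  expect_length(labs_lines, m1$resource_counts$Observation -
                  length(readLines(file.path(d1,
                                             "observation_vitals.ndjson"))))
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  expect_true(file.exists(file.path(d1, "manifest.json")))
  roundtrip <- read_fhir_ndjson(d1)
  expect_identical(length(roundtrip$patient), m1$resource_counts$Patient)
})

test_that("XML output is well-formed FHIR XML", {
  res <- emit_observation(obs_row())
  dir <- withr::local_tempdir()
  sets <- list(observation = structure(list(res), skipped = 0L))
  serialize_resources(sets, dir, format = "xml")
  path <- file.path(dir, paste0("observation-", res$id, ".xml"))
  expect_true(file.exists(path))
  doc <- xml2::read_xml(path)
  expect_identical(xml2::xml_name(doc), "Observation")
  expect_identical(xml2::xml_ns(doc)[[1]], "http://hl7.org/fhir")
  vq <- xml2::xml_find_first(doc, ".//d1:valueQuantity/d1:value")
  expect_identical(xml2::xml_attr(vq, "value"), "7.2")
  comp <- xml2::xml_find_first(doc, ".//d1:valueQuantity/d1:comparator")
  expect_identical(xml2::xml_attr(comp, "value"), "<")
})

test_that("bundle output wraps every resource in one collection", {
  stream <- generate_event_stream(cohort_spec(n_patients = 3, seed = 29))
  sts <- render_pcornet(stream)
  xw <- load_crosswalk(starter_crosswalk_path("pcornet"))
  dir <- withr::local_tempdir()
  manifest <- transform_source(sts, xw, dir, bundle = TRUE)
  b <- jsonlite::fromJSON(file.path(dir, "bundle.json"),
                          simplifyVector = FALSE)
  expect_identical(b$resourceType, "Bundle")
  expect_identical(b$type, "collection")
  expect_length(b$entry,
                sum(unlist(manifest$resource_counts)))
})

test_that("output is referentially closed within one run", {
  stream <- generate_event_stream(cohort_spec(n_patients = 8, seed = 31))
  sts <- render_i2b2(stream)
  xw <- load_crosswalk(starter_crosswalk_path("i2b2"))
  dir <- withr::local_tempdir()
  transform_source(sts, xw, dir)
  sets <- read_fhir_ndjson(dir)
  emitted <- unlist(map(sets, function(res) {
    map_chr(res, function(r) paste0(r$resourceType, "/", r$id))
  }))
  refs <- unlist(map(sets, function(res) map(res, function(r) {
    c(r$subject$reference, r$context$reference)
  })))
  expect_true(all(refs %in% emitted))
})
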