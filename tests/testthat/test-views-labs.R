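# Row-level transformation rules of the two labs views.

test_that("the composite observation identifier concatenates as printed", {
  expect_identical(
    build_obs_identifier(123, 456, "P9", as.Date("2019-01-05"),
                         "LOINC:2345-7", 1),
    "123-456-P9-05-JAN-2019-LOINC:2345-7-1")
  expect_identical(
    build_obs_identifier(1, 1, "P", as.Date("2020-12-31"), "LOINC:X", 2),
    "1-1-P-31-DEC-2020-LOINC:X-2")
  # determinism
  expect_identical(
    build_obs_identifier(1, 1, "P", as.Date("2020-12-31"), "LOINC:X", 2),
    build_obs_identifier(1, 1, "P", as.Date("2020-12-31"), "LOINC:X", 2))
  # a missing part yields NA (the views skip such rows)
  expect_true(is.na(build_obs_identifier(1, NA, "P", as.Date("2020-12-31"),
                                         "LOINC:X", 2)))
})

test_that("the identifier date piece agrees with a locale oracle", {
  dates <- seq(as.Date("2018-01-01"), as.Date("2019-12-31"), by = "37 days")
  expected <- withr::with_locale(c(LC_TIME = "C"),
                                 toupper(format(dates, "%d-%b-%Y")))
  got <- build_obs_identifier(rep(1, length(dates)), 2, "P", dates, "C", 1)
  expect_identical(got, paste0("1-2-P-", expected, "-C-1"))
})

test_that("i2b2 comparator flags map exactly as printed", {
  cases <- list(
    list("N", "E", NA_character_),
    list("N", "L", "<"),
    list("N", "G", ">"),
    list("N", "LE", "<="),
    list("N", "GE", ">="),
    list("T", "LE", NA_character_),  # gated on numeric value type
    list(NA, "LE", NA_character_),
    list("N", NA, NA_character_)
  )
  for (cs in cases) {
    expect_identical(map_i2b2_comparator(cs[[1]], cs[[2]]), cs[[3]],
                     info = paste(cs[[1]], cs[[2]]))
  }
})

test_that("the i2b2 labs view filters, joins and deduplicates as printed", {
  view <- build_labs_view_i2b2(tiny_i2b2())
  # fixture: 5 facts; one ICD10 (prefix filter), one dangling encounter
  # (inner join), two byte-identical LOINC facts (select distinct)
  expect_identical(nrow(view), 2L)
  glu <- view[view$obs_identifier == "1-10-P1-05-JAN-2019-LOINC:2345-7-1", ]
  expect_identical(nrow(glu), 1L)
  expect_identical(glu$obs_subject_reference, "Patient/1")
  expect_identical(glu$obs_context_reference, "Encounter/10")
  expect_identical(glu$obs_code_coding_code, "LOINC:2345-7")
  expect_identical(glu$obs_code_coding_display, "Glucose")
  expect_identical(glu$obs_valuequantity_comparator, "<=")
  expect_identical(glu$obs_valuequantity_value, 7.2)
  expect_identical(glu$obs_category_code, "laboratory")
  expect_identical(glu$obs_code_coding_syst, "http://loinc.org")
  expect_identical(glu$obs_issued, as.Date("2019-01-05"))
  expect_true(is.na(glu$obs_effectivedatetime))
  sk <- attr(view, "skipped")
  expect_identical(sk$n[sk$reason == "no-visit-row"], 1L)
  expect_identical(sk$n[sk$reason == "duplicate-row"], 1L)
})

test_that("i2b2 labs view matches a brute-force cross-product oracle", {
  stream <- generate_event_stream(
    cohort_spec(n_patients = 8, seed = 21,
                edge_case_rates = list(missing_visit = 0.2)))
  sts <- render_i2b2(stream)
  view <- build_labs_view_i2b2(sts)
  # oracle: explicit row scan, no joins
  ofc <- sts$tables$OBSERVATION_FACT
  visits <- sts$tables$VISIT_DIMENSION$ENCOUNTER_NUM
  qualifying <- ofc[startsWith(ofc$CONCEPT_CD, "LOINC"), ]
  expected <- qualifying[qualifying$ENCOUNTER_NUM %in% visits, ]
  expect_identical(nrow(view), nrow(dplyr::distinct(expected)))
  expect_setequal(view$obs_context_reference,
                  paste0("Encounter/", expected$ENCOUNTER_NUM))
  # conservation against the skip ledger
  sk <- attr(view, "skipped")
  expect_identical(nrow(view) + sum(sk$n), attr(view, "n_input"))
})

test_that("display labels use outer-join semantics", {
  tabs <- tiny_i2b2_tables()
  tabs$CONCEPT_DIMENSION <- tabs$CONCEPT_DIMENSION[0, ]
  view <- build_labs_view_i2b2(suppressWarnings(
    new_source_table_set("i2b2", tabs)))
  expect_identical(nrow(view), 2L)  # facts survive a missing concept row
  expect_true(all(is.na(view$obs_code_coding_display)))
})

test_that("valuestring is populated only for text-valued facts", {
  view <- build_labs_view_i2b2(tiny_i2b2())
  txt <- view[!is.na(view$obs_valuestring), ]
  expect_identical(txt$obs_valuestring, "POSITIVE")
  expect_true(is.na(txt$obs_valuequantity_value))
  num <- view[!is.na(view$obs_valuequantity_value), ]
  expect_true(all(is.na(num$obs_valuestring)))
})

test_that("reference-range bounds concatenate the printed modifiers", {
  expect_identical(format_pcornet_ref_range("GE", "3.5"), "GE 3.5")
  expect_identical(format_pcornet_ref_range("LT", "10"), "10")
  expect_identical(format_pcornet_ref_range(NA_character_, NA_character_),
                   NA_character_)
  expect_identical(format_pcornet_ref_range("NO", "5"), "NO 5")
  expect_identical(format_pcornet_ref_range("GE", "3.5", clean = TRUE),
                   "3.5")
  expect_identical(format_pcornet_ref_range("EQ", NA_character_),
                   NA_character_)
})

test_that("sentinel result fields resolve with the printed fallbacks", {
  d1 <- as.Date("2019-01-05"); d2 <- as.Date("2019-01-04")
  r <- resolve_pcornet_result_fields("NI", "NI", "POS", d1, d2)
  expect_true(is.na(r$unit) && is.na(r$valuestring))
  expect_identical(r$effective, d1)
  r <- resolve_pcornet_result_fields("mg/dL", NA, "POSITIVE", as.Date(NA), d2)
  expect_identical(r$unit, "mg/dL")
  expect_identical(r$valuestring, "POSITIVE")
  expect_identical(r$effective, d2)
  r <- resolve_pcornet_result_fields(NA, NA, NA, as.Date(NA), as.Date(NA))
  expect_true(is.na(r$unit) && is.na(r$valuestring) && is.na(r$effective))
})

test_that("the PCORnet labs view translates through the crosswalk", {
  xw <- load_crosswalk(starter_crosswalk_path("pcornet"))
  view <- build_labs_view_pcornet(tiny_pcornet(), xw)
  expect_identical(nrow(view), 2L)
  l1 <- view[view$obs_identifier == "L1", ]
  expect_identical(l1$obs_valuequantity_comparator, "<=")
  expect_identical(l1$obs_interpretation_code, "H")
  expect_identical(l1$obs_interpretation_syst,
                   "http://hl7.org/fhir/ValueSet/observation-interpretation")
  expect_identical(l1$obs_refrange_low, "GE 3.5")
  expect_identical(l1$obs_refrange_high, "10")
  expect_identical(l1$obs_effectivedatetime, as.Date("2019-01-05"))
  l2 <- view[view$obs_identifier == "L2", ]
  # TX modifier has no crosswalk row; NI unit and ABN_IND null out
  expect_true(is.na(l2$obs_valuequantity_comparator))
  expect_true(is.na(l2$obs_valuequantity_code))
  expect_true(is.na(l2$obs_interpretation_code))
  expect_identical(l2$obs_valuestring, "POSITIVE")
  expect_identical(l2$obs_effectivedatetime, as.Date("2019-01-30"))
})

test_that("an empty lab table gives an empty view", {
  sts <- tiny_pcornet()
  sts$tables$LAB_RESULT_CM <- sts$tables$LAB_RESULT_CM[0, ]
  view <- build_labs_view_pcornet(sts, empty_crosswalk())
  expect_identical(nrow(view), 0L)
})

test_that("views are deterministic given identical inputs", {
  stream <- generate_event_stream(cohort_spec(n_patients = 5, seed = 13))
  sts <- render_pcornet(stream)
  xw <- load_crosswalk(starter_crosswalk_path("pcornet"))
  expect_identical(build_labs_view_pcornet(sts, xw),
                   build_labs_view_pcornet(sts, xw))
})
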