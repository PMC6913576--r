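# Summary-statistics validation protocol.

num_extract <- function(values, variable = "lab_x") {
  tibble::tibble(patient_id = as.character(seq_along(values)),
                 variable = variable, type = "numeric",
                 value_num = values, value_chr = NA_character_)
}

test_that("numeric summaries use sample sd and interpolated quartiles", {
  s <- summarize_extract(num_extract(c(1, 2, 3, 4)))
  expect_identical(s$mean, 2.5)
  expect_identical(s$median, 2.5)
  expect_identical(s$q1, 1.75)   # linear interpolation between order stats
  expect_identical(s$q3, 3.25)
  expect_identical(s$n_patients, 4L)
  # closed form: sd of 2,4,4,4,5,5,7,9 is sqrt(32/7)
  s2 <- summarize_extract(num_extract(c(2, 4, 4, 4, 5, 5, 7, 9)))
  expect_equal(s2$sd, sqrt(32 / 7))
  expect_equal(round(s2$sd, 3), 2.138)
  # a single value has no sample sd
  s3 <- summarize_extract(num_extract(5))
  expect_true(is.na(s3$sd))
  expect_identical(s3$mean, 5)
})

test_that("categorical summaries count levels, including missing", {
  ex <- tibble::tibble(
    patient_id = c("1", "2", "3"), variable = "smoking",
    type = "categorical", value_num = NA_real_,
    value_chr = c("A", "A", NA))
  s <- summarize_extract(ex)
  expect_identical(s$levels[[1]], c("(missing)" = 1L, A = 2L))
  expect_identical(s$n_patients, 3L)
})

test_that("identical summaries match 100%, one difference is listed", {
  a <- summarize_extract(num_extract(c(1, 2, 3, 4)))
  expect_identical(compare_summaries(a, a)$match_percentage, 100)
  b <- summarize_extract(num_extract(c(1, 2, 3, 5)))
  rep <- compare_summaries(a, b)
  expect_lt(rep$match_percentage, 100)
  expect_true("lab_x" %in% rep$mismatches$variable)
  expect_true(all(c("source", "fhir") %in% names(rep$mismatches)))
  # extra variable on one side is a mismatch
  b2 <- summarize_extract(dplyr::bind_rows(num_extract(c(1, 2, 3, 4)),
                                           num_extract(7, "lab_y")))
  rep2 <- compare_summaries(a, b2)
  expect_true(any(rep2$mismatches$field == "presence"))
})

test_that("the verdict is symmetric in the arguments", {
  a <- summarize_extract(num_extract(c(1, 2, 3, 4)))
  b <- summarize_extract(dplyr::bind_rows(num_extract(c(1, 2, 3, 5)),
                                          num_extract(7, "lab_y")))
  expect_identical(compare_summaries(a, b)$match_percentage,
                   compare_summaries(b, a)$match_percentage)
})

test_that("flattening FHIR output counts patients per coded condition", {
  dir <- withr::local_tempdir()
  res <- function(id, pat, code) jsonlite::toJSON(list(
    resourceType = "Condition", id = id,
    code = list(coding = list(list(
      system = "http://hl7.org/fhir/sid/icd-10-cm", code = code))),
    subject = list(reference = paste0("Patient/", pat))),
    auto_unbox = TRUE)
  writeLines(c(res("c1", "1", "X10"), res("c2", "2", "X10"),
               res("c3", "3", "Y20")),
             file.path(dir, "condition.ndjson"))
  ex <- flatten_fhir(dir)
  s <- summarize_extract(ex)
  expect_identical(s$n_patients[s$variable == "dx_X10"], 2L)
  expect_identical(s$n_patients[s$variable == "dx_Y20"], 1L)
  # empty directory flattens to an empty extract
  expect_identical(nrow(flatten_fhir(withr::local_tempdir())), 0L)
})

test_that("malformed NDJSON is fatal with the line number", {
  dir <- withr::local_tempdir()
  writeLines(c("{\"resourceType\":\"Patient\",\"id\":\"1\"}", "{broken"),
             file.path(dir, "patient.ndjson"))
  expect_error(flatten_fhir(dir), "line 2")
})

test_that("a lossless cohort matches 100% end to end", {
  stream <- generate_event_stream(lossless_spec(n_patients = 15, seed = 33))
  sts <- render_pcornet(stream)
  xw <- load_crosswalk(starter_crosswalk_path("pcornet"))
  dir <- withr::local_tempdir()
  transform_source(sts, xw, dir)
  rep <- compare_summaries(summarize_extract(flatten_source(sts, xw)),
                           summarize_extract(flatten_fhir(dir)))
  expect_identical(rep$match_percentage, 100)
  expect_identical(nrow(rep$mismatches), 0L)
})

test_that("the i2b2 path also matches 100% on a lossless cohort", {
  stream <- generate_event_stream(lossless_spec(n_patients = 12, seed = 34))
  sts <- render_i2b2(stream)
  xw <- load_crosswalk(starter_crosswalk_path("i2b2"))
  dir <- withr::local_tempdir()
  transform_source(sts, xw, dir, strip_prefix = TRUE)
  rep <- compare_summaries(summarize_extract(flatten_source(sts, xw)),
                           summarize_extract(flatten_fhir(dir)))
  expect_identical(rep$match_percentage, 100)
})

test_that("unmappable encounter types surface as an observable mismatch", {
  stream <- generate_event_stream(cohort_spec(
    n_patients = 10, seed = 35,
    edge_case_rates = list(unmappable_encounter = 1, multiple_race = 0,
                           missing_visit = 0)))
  sts <- render_pcornet(stream)
  xw <- load_crosswalk(starter_crosswalk_path("pcornet"))
  dir <- withr::local_tempdir()
  transform_source(sts, xw, dir)
  rep <- compare_summaries(summarize_extract(flatten_source(sts, xw)),
                           summarize_extract(flatten_fhir(dir)))
  expect_lt(rep$match_percentage, 100)
  expect_true("encounter_class" %in% rep$mismatches$variable)
})

test_that("the medication crosswalk hook translates local ids on the source side", {
  sts <- tiny_pcornet()
  sts$tables$PRESCRIBING$RXNORM_CUI <- "LOCALMED7"
  xw <- load_crosswalk(starter_crosswalk_path("pcornet"))
  ex_raw <- flatten_source(sts, xw)
  expect_true("med_LOCALMED7" %in% ex_raw$variable)
  ex_mapped <- flatten_source(sts, xw,
                              med_code_map = c(LOCALMED7 = "435"))
  expect_true("med_435" %in% ex_mapped$variable)
  expect_false("med_LOCALMED7" %in% ex_mapped$variable)
})

test_that("tidy, glance and autoplot expose the report", {
  a <- summarize_extract(num_extract(c(1, 2, 3, 4)))
  b <- summarize_extract(num_extract(c(1, 2, 3, 5)))
  rep <- compare_summaries(a, b)
  expect_identical(tidy(rep), rep$comparison)
  g <- glance(rep)
  expect_identical(g$n_variables, 1L)
  expect_identical(g$match_percentage, rep$match_percentage)
  expect_s3_class(autoplot(rep), "ggplot")
})
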