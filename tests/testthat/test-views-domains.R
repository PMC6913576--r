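# The non-labs views: crosswalk-driven class/demographic codes, documented
# lossy mappings, and fields with no FHIR equivalent.

xw_i <- load_crosswalk(starter_crosswalk_path("i2b2"))
xw_p <- load_crosswalk(starter_crosswalk_path("pcornet"))

test_that("encounter class maps where FHIR has an equivalent, else null", {
  enc_i <- build_encounter_view(tiny_i2b2(), xw_i)
  expect_identical(enc_i$enc_class_code[enc_i$enc_identifier == "10"], "IMP")
  expect_identical(enc_i$enc_class_code[enc_i$enc_identifier == "11"], "AMB")
  enc_p <- build_encounter_view(tiny_pcornet(), xw_p)
  expect_identical(enc_p$enc_class_code[enc_p$enc_identifier == "10"], "IMP")
  # EI (ED admit to inpatient) has no FHIR equivalent
  expect_true(is.na(enc_p$enc_class_code[enc_p$enc_identifier == "11"]))
})

test_that("discharge disposition and admitting source translate with nulls", {
  enc <- build_encounter_view(tiny_pcornet(), xw_p)
  ip <- enc[enc$enc_identifier == "10", ]
  expect_identical(ip$enc_dischargedisposition_code, "home")
  expect_identical(ip$enc_dischargedisposition_syst,
                   "http://hl7.org/fhir/discharge-disposition")
  expect_identical(ip$enc_admitsource_code, "emd")
  other <- enc[enc$enc_identifier == "11", ]  # NI sentinels
  expect_true(is.na(other$enc_dischargedisposition_code))
  expect_true(is.na(other$enc_admitsource_code))
})

test_that("multiple-race patients come out with no race code", {
  pat <- build_patient_view(tiny_pcornet(), xw_p)
  p1 <- pat[pat$pat_identifier == "1", ]
  expect_identical(p1$pat_race_code, "2106-3")
  expect_identical(p1$pat_gender_code, "female")
  p2 <- pat[pat$pat_identifier == "2", ]  # RACE "06" = multiple race
  expect_true(is.na(p2$pat_race_code))
  expect_identical(p2$pat_ethnicity_code, "2135-2")
  pat_i <- build_patient_view(tiny_i2b2(), xw_i)
  expect_true(is.na(pat_i$pat_race_code[pat_i$pat_identifier == "2"]))
})

test_that("condition, procedure and medication views carry their systems", {
  cond <- build_condition_view(tiny_pcornet(), xw_p)
  expect_identical(cond$cond_code_coding_code, "J45.40")
  expect_identical(cond$cond_code_coding_syst,
                   "http://hl7.org/fhir/sid/icd-10-cm")
  proc <- build_procedure_view(tiny_pcornet(), xw_p)
  expect_identical(proc$proc_code_coding_code, "99213")
  med <- build_medrequest_view(tiny_pcornet(), xw_p)
  expect_identical(med$medreq_medication_code, "435")
  expect_identical(med$medreq_medication_syst,
                   "http://www.nlm.nih.gov/research/umls/rxnorm")
  cond_i <- build_condition_view(tiny_i2b2(), xw_i)
  expect_identical(cond_i$cond_code_coding_code, "ICD10:J45.40")
  cond_is <- build_condition_view(tiny_i2b2(), xw_i, strip_prefix = TRUE)
  expect_identical(cond_is$cond_code_coding_code, "J45.40")
})

test_that("vitals view codes height, weight and smoking with fixed LOINCs", {
  vit <- build_vitals_view(tiny_pcornet(), xw_p)
  expect_setequal(vit$obs_code_coding_code,
                  c("8302-2", "29463-7", "72166-2"))
  expect_true(all(vit$obs_category_code == "vital-signs"))
  ht <- vit[vit$obs_code_coding_code == "8302-2", ]
  expect_identical(ht$obs_valuequantity_value, 66.1)
  expect_identical(ht$obs_valuequantity_code, "in")
  sm <- vit[vit$obs_code_coding_code == "72166-2", ]
  expect_identical(sm$obs_valuecodeableconcept_code, "266919005")
  expect_identical(sm$obs_valuecodeableconcept_syst,
                   "http://snomed.info/sct")
})

test_that("unmappable smoking descriptors leave the coded value empty", {
  sts <- tiny_pcornet()
  sts$tables$VITAL$SMOKING <- "OT"
  vit <- build_vitals_view(sts, xw_p)
  sm <- vit[vit$obs_code_coding_code == "72166-2", ]
  expect_identical(nrow(sm), 1L)  # the loss is observable, not silent
  expect_true(is.na(sm$obs_valuecodeableconcept_code))
})

test_that("fields with no FHIR equivalent are never consumed", {
  sts <- tiny_pcornet()
  base <- build_views(sts, xw_p)
  sts$tables$DEMOGRAPHIC$SEXUAL_ORIENTATION <- "ZZ"
  sts$tables$DEMOGRAPHIC$GENDER_IDENTITY <- "ZZ"
  sts$tables$DEMOGRAPHIC$BIOBANK_FLAG <- "ZZ"
  sts$tables$DIAGNOSIS$DX_POA <- "ZZ"
  sts$tables$DIAGNOSIS$DX_ORIGIN <- "ZZ"
  sts$tables$PROCEDURES$PX_SOURCE <- "ZZ"
  sts$tables$VITAL$VITAL_SOURCE <- "ZZ"
  sts$tables$VITAL$BP_POSITION <- "ZZ"
  sts$tables$VITAL$TOBACCO <- "ZZ"
  sts$tables$VITAL$TOBACCO_TYPE <- "ZZ"
  sts$tables$LAB_RESULT_CM$RESULT_LOC <- "ZZ"
  sts$tables$PRESCRIBING$RX_SOURCE <- "ZZ"
  perturbed <- build_views(sts, xw_p)
  expect_identical(perturbed, base)
})

test_that("every reference column carries its resource-type prefix", {
  stream <- generate_event_stream(cohort_spec(n_patients = 6, seed = 17))
  for (sts in list(render_i2b2(stream), render_pcornet(stream))) {
    xw <- if (sts$model == "i2b2") xw_i else xw_p
    views <- build_views(sts, xw)
    for (v in views) {
      for (cn in grep("subject_reference$", names(v), value = TRUE)) {
        expect_true(all(startsWith(v[[cn]], "Patient/")))
      }
      for (cn in grep("context_reference$", names(v), value = TRUE)) {
        expect_true(all(startsWith(v[[cn]], "Encounter/")))
      }
    }
  }
})

test_that("no view row references a patient or encounter absent from source", {
  stream <- generate_event_stream(cohort_spec(n_patients = 6, seed = 18))
  sts <- render_pcornet(stream)
  views <- build_views(sts, xw_p)
  pats <- paste0("Patient/", sts$tables$DEMOGRAPHIC$PATID)
  encs <- paste0("Encounter/", sts$tables$ENCOUNTER$ENCOUNTERID)
  for (v in views) {
    for (cn in grep("subject_reference$", names(v), value = TRUE)) {
      expect_true(all(v[[cn]] %in% pats))
    }
    for (cn in grep("context_reference$", names(v), value = TRUE)) {
      expect_true(all(v[[cn]] %in% encs))
    }
  }
})
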