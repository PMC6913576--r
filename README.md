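# cdm2fhir

Clinical research collaborations rarely share a common data model: one site
keeps its EHR extract in an i2b2 star schema, another in the PCORnet CDM,
and pooling their data means either standing up a new warehouse or writing
one-off converters. `cdm2fhir` treats HL7 FHIR STU3 (3.0.1) as the neutral
exchange model instead: it reads either source model from plain CSV tables,
normalizes them through a documented intermediate **view layer**, translates
local codes through a single **value-set crosswalk**, and writes valid FHIR
resources (Patient, Encounter, Condition, Procedure, Observation,
MedicationRequest, Practitioner) as newline-delimited JSON or XML. It is
aimed at informaticians provisioning cohort-scale extracts for downstream
analysis, not at running a FHIR server.

## The transformation in brief

Each clinical domain is flattened to a view with fixed `DOMAINPREFIX_FIELD`
columns; FHIR emission is then a mechanical mapping from view columns to
resource elements. Two ideas carry the whole design:

1. **The view layer is the mapping boundary.** All source-model knowledge
   lives in the view builders. For i2b2 the laboratory view selects distinct
   facts with `CONCEPT_CD LIKE 'LOINC%'`, inner-joins the visit dimension
   (facts without a visit are dropped and logged), outer-joins the concept
   dimension for display labels, builds the composite identifier
   `patient-encounter-provider-DD-MON-YYYY-concept-instance`, and maps the
   `(VALTYPE_CD, TVAL_CHAR)` pairs `(N, L/G/LE/GE)` to the quantity
   comparators `< > <= >=` (with `E` meaning no comparator). For PCORnet it
   reads `LAB_RESULT_CM` one row per record, resolves the `NI`
   (no-information) sentinels to nulls, takes `RESULT_QUAL` with
   `RAW_RESULT` as fallback, `SPECIMEN_DATE` with `LAB_ORDER_DATE` as
   fallback, and renders normal-range bounds as
   `<modifier> <bound>` for the modifiers `EQ/GE/GT/NO`.
2. **Unmappable codes become null, visibly.** Value-set translation is an
   exact lookup in a five-column crosswalk
   (`TABLE_CD, COLUMN_CD, LOCAL_IN_CD, FHIR_OUT_CD, FHIR_SYSTEM`). A local
   code with no row — a multiple-race patient, an `EI` encounter type, an
   `NI/UN/OT` sentinel — yields an absent FHIR element, and every miss is
   tallied per source column in the run manifest. No custom value sets or
   extensions are invented to paper over the gaps.

A seeded synthetic-cohort generator renders one clinical event stream as
*both* source models, which makes the pipeline testable end to end: the two
renderings must produce tuple-identical FHIR output, and a
summary-statistics validator (patient counts, means, standard deviations,
quartiles, level counts, compared variable by variable between the source
extract and the FHIR-derived extract) must report a 100% match on a cohort
restricted to losslessly mappable fields.

## Worked example

From R, the whole pipeline is three calls:

```r
library(cdm2fhir)
stream <- generate_event_stream(cohort_spec(n_patients = 5, seed = 3))
sts    <- render_pcornet(stream)
xw     <- load_crosswalk(starter_crosswalk_path("pcornet"))
manifest <- transform_source(sts, xw, "fhir_out")
print(manifest)
```

```
<fhir_manifest> format: json
 resource counts:
   Patient                 5
   Encounter              18
   Practitioner           10
   Condition              26
   Procedure               4
   Observation            89
   MedicationRequest      11
 crosswalk misses:
   LAB_RESULT_CM.ABN_IND              31
   LAB_RESULT_CM.RESULT_MODIFIER      38
```

Five patients yielded 18 encounters and 89 observations (labs plus
height/weight/smoking vitals). The miss tallies are expected: most lab
results are neither abnormal (`ABN_IND = "NI"`) nor comparator-coded
(`RESULT_MODIFIER = "EQ"`), and neither sentinel has a crosswalk row, so
those elements are absent from the emitted Observations. Validating the
run against its own source tables:

```r
rep <- run_validation("source_dir", "pcornet", "fhir_out")
print(rep)
#> <validation_report> 62 variables, 100.0% matched
```

The same commands are available from a shell via the bundled CLI
(`inst/cli/cdm2fhir`): `cdm2fhir generate | transform | validate`, with
flags like `--strip-code-prefix` (drop `LOINC:`-style prefixes from i2b2
codes), `--clean-ref-ranges`, `--bundle`, `--dump-views`, and a
`cdm2fhir.yaml` config file (flag > file > default).

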