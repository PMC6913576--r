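---
title: "Mapping i2b2 and PCORnet to FHIR STU3: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping i2b2 and PCORnet to FHIR STU3: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdm2fhir)
```

## The problem and the shape of the solution

Electronic-health-record extracts live in relational common data models:
the i2b2 star schema keeps almost everything in one fact table
(`OBSERVATION_FACT`) keyed against patient, visit, concept and provider
dimensions; the PCORnet CDM v4.1 normalizes each domain into its own table
(`DEMOGRAPHIC`, `ENCOUNTER`, `LAB_RESULT_CM`, ...) with strictly enumerated
value sets. FHIR, by contrast, is a serialized exchange standard. Any
CDM-to-FHIR transformation therefore has two separable tasks: mapping each
source variable to a FHIR element, and mapping each member of a coded value
set to the corresponding FHIR value-set member.

`cdm2fhir` keeps these tasks in two artifacts. Variable mapping lives in
*views*: per-domain flat tables with `DOMAINPREFIX_FIELD` columns
(`OBS_IDENTIFIER`, `ENC_CLASS_CODE`, ...) built by model-specific builders
but identical in shape across models, so FHIR emission downstream of the
views is source-agnostic. Value-set mapping lives in one five-column
crosswalk table; code translation is an exact, case-sensitive,
whitespace-trimmed lookup, and a miss produces a null (an absent element in
the emitted resource), never an error and never a made-up code. Both
choices favor auditability: the views can be dumped as CSV
(`--dump-views`), and every crosswalk miss is tallied per source column in
the run manifest, because mapped-to-null losses can be scientifically
significant and must be visible.

## Row-level rules worth stating precisely

*i2b2 laboratory view.* Facts qualify by concept prefix (default
`"LOINC"`, configurable for sites with other ontologies). Qualifying facts
are deduplicated (`select distinct` semantics), inner-joined to the visit
dimension — a fact whose `ENCOUNTER_NUM` has no visit row is dropped and
logged, not invented — and outer-joined to the concept dimension, so a
missing concept row costs only the display label. The record identifier is
the hyphen-joined composite of patient, encounter, provider, date, concept
and repeat index, with the date rendered `DD-MON-YYYY` using fixed
upper-case English month abbreviations regardless of locale (identifiers
must be reproducible across systems). Comparator flags on numeric facts map
`L/G/LE/GE` to `</>/<=/>=`; `E` (equals) maps to no comparator; the flags
are ignored for text-valued facts. The fact date is emitted as `issued`;
`effectiveDateTime` stays empty in the i2b2 view — both are emitted exactly
as the view defines them, and consumers can prefer either.

*PCORnet laboratory view.* One view row per `LAB_RESULT_CM` record, keyed
by the table's own row id. The `NI` (no-information) sentinel nulls the
unit and the qualitative result; `RESULT_QUAL` falls back to `RAW_RESULT`,
`SPECIMEN_DATE` to `LAB_ORDER_DATE`. Comparators and abnormal-result flags
are translated through the crosswalk (`RESULT_MODIFIER`, `ABN_IND`).
Normal-range bounds are rendered by concatenating the range modifier in
front of the bound for the modifier codes `EQ`, `GE`, `GT` and `NO`, and
emitting the bare bound otherwise. Two deliberate quirks: the
no-information modifier `NO` *is* concatenated into the range string,
replicating the staging rule as defined, with `clean_ref_ranges = TRUE` as
the opt-in normalization; and since the bounds are strings once a modifier
is attached, the emitted Observation carries them in `referenceRange.text`
(the STU3 `low`/`high` elements are Quantities and cannot hold `"GE 3.5"`).

*Other domains.* Patient, Encounter, Condition, Procedure,
MedicationRequest, Practitioner and the vitals Observations follow the same
conventions; their column rosters are the package's own view contract
(printed by `build_views()`). Vitals are coded with the standard LOINCs
(8302-2 height, 29463-7 weight, 72166-2 smoking status); smoking
descriptors translate through the crosswalk to SNOMED CT coded values.
PCORnet fields with no FHIR equivalent (`SEXUAL_ORIENTATION`,
`GENDER_IDENTITY`, `BIOBANK_FLAG`, `DX_ORIGIN`, `DX_POA`, `PX_SOURCE`,
`VITAL_SOURCE`, `BP_POSITION`, `TOBACCO`, `TOBACCO_TYPE`, `RESULT_LOC`,
`RX_SOURCE`) are declared in the schema and never consumed — the test suite
perturbs them and asserts identical output. Race and ethnicity have no core
Patient element; they are emitted via the US-Core extension pair only when
the crosswalk supplies a code and system, and dropped (observably) when it
does not.

## Emission and serialization

Resources are nested lists shaped by the STU3 3.0.1 definitions. Where
STU3 requires a status the source models do not record, fixed values are
supplied: Observation `final`, Encounter `finished`, Procedure `completed`,
MedicationRequest `intent = "order"` / `status = "completed"`. Source dates
are timezone-naive calendar dates; `Observation.issued` is an FHIR
`instant` and is serialized as midnight UTC. Resource ids reuse the view
identifier with characters outside `[A-Za-z0-9.-]` replaced by `"."`
(composite i2b2 identifiers contain colons); ids longer than 64 characters
are truncated with a short content-hash suffix. References use the
sanitized ids consistently, and patients, encounters and practitioners are
emitted before the resources that reference them, so one run's output is
referentially closed. JSON output is newline-delimited per domain (diffable
and streamable; `--bundle` wraps a collection Bundle instead); XML output
is one FHIR-XML file per resource. Serialization is deterministic:
identical inputs give byte-identical files.

Structural validity is checked by a table-driven validator interpreting a
bundled snapshot of the STU3 structural definitions for the seven supported
types (element whitelists, required elements, primitive shapes, array
cardinality, codings carrying system and code together, no null-valued
elements). The tables are data, not emitter code, so the check is an
independent oracle in the test suite.

## The synthetic cohort: what it emulates and what it does not

The generator draws one model-agnostic event stream — patients with
demographics, encounters with class and disposition, labs, diagnoses
(ICD-10-CM), procedures (CPT), medications (RxNorm), vitals — and renders
it into both schemas. Code identifiers come from fixed bundled pools
(about 30 LOINC, 30 ICD-10-CM, 20 RxNorm, 10 CPT codes) with plausible
per-analyte normal ranges; the values are synthetic and in no way
clinically validated. Defaults: 200 patients, a 2015–2019 window, mean
counts per patient of 4 encounters, 10 labs, 4 diagnoses, 2 procedures,
3 medications, 3 vitals — a deliberately small, laptop-scale cohort that
still populates every domain.

Edge-case injection reproduces the data properties the transformation
rules exist for, with default rates chosen as "common enough to always be
exercised, rare enough to stay realistic": comparator-coded labs 0.10,
missing units 0.10, text-valued labs 0.10, unmappable encounter types 0.05,
multiple-race patients 0.05. Text and comparator labs are disjoint
categories of one draw, so the configured rates are exact expected
fractions. The missing-visit-link rate defaults to 0: it is the one
asymmetric injection (PCORnet enforces encounter referential integrity, so
a dangling link can only be rendered in i2b2), and the package's
cross-model equivalence property — both renderings of one stream produce
FHIR outputs with identical (subject, code, value, comparator, unit, date)
tuples — is stated over the default conditions. Tests exercise dangling
links explicitly at nonzero rates. Randomness comes from R's RNG seeded
per call (`withr::with_seed`), leaving global state untouched.

What the generator does not emulate: longitudinal disease dynamics,
realistic epidemiology or code co-occurrence, free-text notes, unit
heterogeneity for one analyte, duplicated or contradictory source rows
beyond exact duplicates, or local ontology drift. A 100% pass on synthetic
data therefore demonstrates the *mechanics* of transformation and
validation, not robustness to every idiosyncrasy of a production
warehouse.

## The validation protocol

For each variable — demographics, one numeric series per observation code,
qualitative results, smoking status, diagnosis/medication presence,
encounter class — summary statistics are computed twice: from the FHIR
output and from a source-of-truth extract taken directly off the source
tables. Numeric variables use the sample standard deviation (undefined
below two records, reported as null) and quartiles by linear interpolation
between order statistics (R's default type 7), fixed and documented so the
numbers are reproducible across languages. Categorical variables are
compared as exact level-count maps. Numeric comparison is near-exact
(relative tolerance `1e-9`, configurable) since both sides are computed
from the same stored doubles; values survive the JSON round trip because
serialization never rounds.

One asymmetry is intentional: the source extract translates coded values
through the crosswalk *where a mapping exists* but keeps untranslatable
local codes verbatim, while the FHIR side carries nulls for them (counted
under a `"(missing)"` level). A lossy mapping therefore shows up as a
level-count mismatch instead of disappearing from both sides — on a cohort
of only unmappable encounter types, the encounter-class variable fails the
comparison, by design. The medication comparison accepts an optional local
to-standard id map (`med_code_map`) for sites whose warehouse codes
medications with internal ids rather than RxNorm.

## Bundled reference data

The crosswalk outputs are pinned against offline snapshots of the value
sets they target: the v3 ActEncounterCode classes (11 codes), encounter
discharge disposition (11 codes, including the alternative-home code),
admitting source (10), an observation-interpretation subset, quantity
comparators, administrative gender, the CDC race/ethnicity codes and a
SNOMED CT smoking-status subset — plus the PCORnet v4.1 local
`DISCHARGE_STATUS` (17 values) and `ADMITTING_SOURCE` (16 values) sets.
The 17-versus-11 and 16-versus-10 gaps are exactly why discharge
disposition and admitting source are documented lossy mappings. The i2b2
starter crosswalk records the ActEncounterCode system as the STU3
documentation URL string; the package reproduces that string verbatim in
its starter file (substituting the canonical URI would silently change
emitted data) and treats it as an alias of the canonical v3 system when
checking membership.

## Numerical and degenerate-input choices

* Empty CSV fields are nulls; dates are ISO 8601, any time part dropped,
  all handling timezone-naive.
* Referential integrity is checked eagerly at load: unknown patients (both
  models) and unknown PCORnet encounter ids are fatal with the orphan keys
  listed. Dangling i2b2 fact-to-visit links warn instead — the labs view's
  inner join is the documented mechanism that excludes them, and they are a
  legitimate data condition the generator can inject.
* Row-level failures inside a view (e.g. a missing identifier part) skip
  the row and log a reason code; they never abort a cohort-scale run.
  Emitted + skipped always equals the qualifying input count.
* Empty tables flow through: empty views, empty resource lists, an empty
  extract, a 100% match on zero variables.
* View output is ordered by identifier; ties cannot occur because
  identifiers are unique within a run (enforced per view).

## Problem sizes and limitations

The test suite and the acceptance script run on 200-patient cohorts
(roughly 7,000 resources end to end), which the package's own profiling
puts at well under two minutes per full pipeline on a single core; the
sizes are a package choice balancing coverage against turnaround. Known
limitations: FHIR STU3 only (no R4), seven resource types, no OMOP input,
no laboratory unit harmonization, no semantic parsing of reference ranges
beyond the documented concatenation, no handling of the PCORnet tables that
cannot be mapped at all (`PRO_CM`, `DEATH_CAUSE`, `DISPENSING`,
`OBS_GEN`), and no terminology-server integration — the crosswalk is the
single, local source of code translations.
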