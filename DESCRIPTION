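Package: cdm2fhir
Title: Transform i2b2 and PCORnet Clinical Data Models to FHIR STU3
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A source-agnostic engine that transforms clinical data stored in
    the i2b2 star schema or the PCORnet Common Data Model v4.1 into HL7 FHIR
    STU3 (3.0.1) resources. Source tables are loaded from delimited files,
    normalized through a documented intermediate view layer, translated
    against a value-set crosswalk with null-on-unmappable semantics, and
    serialized as newline-delimited JSON or XML. Includes a seeded synthetic
    cohort generator that renders the same clinical event stream in both
    source models, a table-driven STU3 structural validator, and a
    summary-statistics validation protocol that compares a source-of-truth
    extract against the FHIR-derived extract variable by variable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
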