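# Cross-model equivalence: for one clinical event stream rendered in both
# source models, the FHIR outputs must agree on the model-independent
# content. Identifiers are excluded (their construction differs by model:
# composite keys in i2b2, table row ids in PCORnet), as are fields only one
# model records at source (e.g. vital status, reference ranges,
# interpretation flags).

#' Extract model-independent comparison tuples from emitted resources
#'
#' Produces, per domain, the sorted multiset of tuples that should be
#' identical across source models: observations as (subject, code, value,
#' comparator, unit, coded value, date), conditions / procedures /
#' medication requests as (subject, code, date), encounters as (subject,
#' class, start, end), patients as (id, gender, birth date, race,
#' ethnicity) and practitioners as (id, name).
#'
#' @param resource_sets Named list of resource lists (from [emit_domain()]
#'   or [read_fhir_ndjson()]).
#' @return Named list of sorted tibbles: `observation`, `condition`,
#'   `procedure`, `medicationrequest`, `encounter`, `patient`,
#'   `practitioner`.
#' @export
fhir_equivalence_tuples <- function(resource_sets) {
  g <- function(x) x %||% NA_character_
  date10 <- function(x) if (is.null(x)) NA_character_ else substr(x, 1, 10)
  obs <- c(resource_sets$observation_labs %||% list(),
           resource_sets$observation_vitals %||% list(),
           resource_sets$observation %||% list())
  observation <- list_rbind(map(obs, function(r) tibble(
    subject = g(r$subject$reference),
    code = g(r$code$coding[[1]]$code),
    value = r$valueQuantity$value %||% NA_real_,
    comparator = g(r$valueQuantity$comparator),
    unit = g(r$valueQuantity$unit),
    value_code = g(r$valueCodeableConcept$coding[[1]]$code),
    value_text = g(r$valueString),
    date = date10(r$issued)
  )))
  coded <- function(res, code_fun, date_fun) {
    list_rbind(map(res %||% list(), function(r) tibble(
      subject = g(r$subject$reference),
      code = g(code_fun(r)),
      date = date10(date_fun(r))
    )))
  }
  out <- list(
    observation = observation,
    condition = coded(resource_sets$condition,
                      function(r) r$code$coding[[1]]$code,
                      function(r) r$onsetDateTime),
    procedure = coded(resource_sets$procedure,
                      function(r) r$code$coding[[1]]$code,
                      function(r) r$performedDateTime),
    medicationrequest = coded(resource_sets$medicationrequest,
                              function(r) r$medicationCodeableConcept$coding[[1]]$code,
                              function(r) r$authoredOn),
    encounter = list_rbind(map(resource_sets$encounter %||% list(),
      function(r) tibble(
        subject = g(r$subject$reference),
        class = g(r$class$code),
        start = g(r$period$start),
        end = g(r$period$end)))),
    patient = list_rbind(map(resource_sets$patient %||% list(),
      function(r) {
        ext_code <- function(url) {
          for (e in r$extension %||% list()) {
            if (identical(e$url, url)) {
              return(e$extension[[1]]$valueCoding$code %||% NA_character_)
            }
          }
          NA_character_
        }
        tibble(
          id = g(r$id),
          gender = g(r$gender),
          birth = g(r$birthDate),
          race = ext_code("http://hl7.org/fhir/us/core/StructureDefinition/us-core-race"),
          ethnicity = ext_code("http://hl7.org/fhir/us/core/StructureDefinition/us-core-ethnicity"))
      })),
    practitioner = list_rbind(map(resource_sets$practitioner %||% list(),
      function(r) tibble(
        id = g(r$id),
        name = g(r$name[[1]]$text))))
  )
  map(out, function(tb) {
    if (is.null(tb) || nrow(tb) == 0L) return(tb)
    arrange(tb, dplyr::across(dplyr::everything()))
  })
}
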