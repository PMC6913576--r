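#' Load a source table set from a directory of CSV files
#'
#' Reads one CSV per table of the declared model (`OBSERVATION_FACT.csv`,
#' `PATIENT_DIMENSION.csv`, ... for i2b2; `DEMOGRAPHIC.csv`, `ENCOUNTER.csv`,
#' ... for PCORnet), validates every table against its schema, checks
#' referential and domain invariants eagerly, and optionally restricts the
#' set to a cohort of patient identifiers.
#'
#' Files are comma-separated UTF-8 with a header row; header matching is
#' case-insensitive and columns are canonicalized to upper case. Empty fields
#' are parsed as missing. Dates must be ISO 8601 (`YYYY-MM-DD`, an optional
#' time part is dropped).
#'
#' @param dir_path Directory holding one CSV file per table.
#' @param model `"i2b2"` or `"pcornet"`.
#' @param cohort_file Optional path to a text file with one patient id per
#'   line; when given, every table is restricted to those patients.
#' @param cohort Optional character vector of patient ids (alternative to
#'   `cohort_file`).
#' @return A `source_table_set`: a list with elements `model`, `tables`
#'   (named list of tibbles) and `cohort` (character vector of patient ids).
#' @export
#' @examples
#' stream <- generate_event_stream(cohort_spec(n_patients = 3, seed = 1))
#' dir <- file.path(tempdir(), "i2b2demo")
#' write_source_csv(render_i2b2(stream), dir)
#' sts <- load_source(dir, "i2b2")
#' nrow(sts$tables$PATIENT_DIMENSION)
load_source <- function(dir_path, model, cohort_file = NULL, cohort = NULL) {
  model <- match.arg(model, c("i2b2", "pcornet"))
  schema <- cdm_schema(model)
  if (!dir.exists(dir_path)) {
    abort(paste0("Source directory not found: ", dir_path))
  }
  tables <- list()
  for (tab in names(schema)) {
    path <- file.path(dir_path, paste0(tab, ".csv"))
    if (!file.exists(path)) {
      # tolerate lower-case file names
      alt <- file.path(dir_path, paste0(tolower(tab), ".csv"))
      if (file.exists(alt)) path <- alt
    }
    if (!file.exists(path)) {
      abort(paste0("Missing required table file for ", model, ": ", tab,
                   " (expected ", tab, ".csv in ", dir_path, ")"))
    }
    tables[[tab]] <- read_cdm_table(path, tab, schema[[tab]]$cols)
  }
  if (!is.null(cohort_file)) {
    if (!is.null(cohort)) {
      abort("Give either `cohort_file` or `cohort`, not both.")
    }
    cohort <- readLines(cohort_file, warn = FALSE)
    cohort <- trimws(cohort)
    cohort <- cohort[nzchar(cohort)]
  }
  new_source_table_set(model, tables, cohort)
}

#' Construct and validate a source table set from in-memory tables
#'
#' @param model `"i2b2"` or `"pcornet"`.
#' @param tables Named list of tibbles, one per table of the model's schema.
#' @param cohort Optional character vector of patient ids to restrict to;
#'   `NULL` keeps all patients.
#' @return A validated `source_table_set`.
#' @export
new_source_table_set <- function(model, tables, cohort = NULL) {
  model <- match.arg(model, c("i2b2", "pcornet"))
  schema <- cdm_schema(model)
  missing_tabs <- setdiff(names(schema), names(tables))
  if (length(missing_tabs)) {
    abort(paste0("Missing required table(s) for ", model, ": ",
                 paste(missing_tabs, collapse = ", ")))
  }
  tables <- tables[names(schema)]
  tables <- imap(tables, function(tb, nm) {
    coerce_cdm_table(as_tibble(tb), nm, schema[[nm]]$cols)
  })
  sts <- structure(
    list(model = model, tables = tables, cohort = NULL),
    class = "source_table_set"
  )
  validate_source_tables(sts)
  if (!is.null(cohort)) sts <- filter_cohort(sts, cohort)
  sts
}

patient_ids <- function(sts) {
  if (sts$model == "i2b2") {
    sts$tables$PATIENT_DIMENSION$PATIENT_NUM
  } else {
    sts$tables$DEMOGRAPHIC$PATID
  }
}

#' Restrict a source table set to a cohort of patients
#'
#' Filtering is idempotent and monotone: filtering by `s` and then by a
#' subset `s2` of `s` gives the same result as filtering by `s2` directly.
#'
#' @param sts A `source_table_set`.
#' @param cohort Character vector of patient ids; must all be present.
#' @return The filtered `source_table_set`, with `$cohort` recorded.
#' @export
filter_cohort <- function(sts, cohort) {
  stopifnot(inherits(sts, "source_table_set"))
  cohort <- unique(as.character(cohort))
  unknown <- setdiff(cohort, patient_ids(sts))
  if (length(unknown)) {
    abort(paste0("Cohort ids not present in the patient table: ",
                 paste(head(unknown, 10), collapse = ", ")))
  }
  key_of <- function(nm) {
    cols <- names(sts$tables[[nm]])
    if ("PATIENT_NUM" %in% cols) "PATIENT_NUM"
    else if ("PATID" %in% cols) "PATID"
    else NA_character_
  }
  sts$tables <- imap(sts$tables, function(tb, nm) {
    key <- key_of(nm)
    if (is.na(key)) return(tb)
    tb[tb[[key]] %in% cohort, , drop = FALSE]
  })
  sts$cohort <- cohort
  sts
}

#' @export
print.source_table_set <- function(x, ...) {
  cat("<source_table_set> model:", x$model, "\n")
  for (nm in names(x$tables)) {
    cat(sprintf("  %-20s %6d rows\n", nm, nrow(x$tables[[nm]])))
  }
  cat("  cohort:", if (is.null(x$cohort)) "all patients"
      else paste(length(x$cohort), "patients"), "\n")
  invisible(x)
}

# -- reading / writing --------------------------------------------------------

read_cdm_table <- function(path, table_name, cols) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = c(""), progress = FALSE, show_col_types = FALSE
  )
  names(raw) <- toupper(names(raw))
  unknown <- setdiff(names(raw), names(cols))
  if (length(unknown)) {
    abort(paste0("Unknown column(s) in ", table_name, ": ",
                 paste(unknown, collapse = ", ")))
  }
  coerce_cdm_table(raw, table_name, cols)
}

coerce_cdm_table <- function(tb, table_name, cols) {
  names(tb) <- toupper(names(tb))
  missing_cols <- setdiff(names(cols), names(tb))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s) in ", table_name, ": ",
                 paste(missing_cols, collapse = ", ")))
  }
  unknown <- setdiff(names(tb), names(cols))
  if (length(unknown)) {
    abort(paste0("Unknown column(s) in ", table_name, ": ",
                 paste(unknown, collapse = ", ")))
  }
  tb <- tb[names(cols)]
  for (cn in names(cols)) {
    tb[[cn]] <- coerce_cdm_column(tb[[cn]], cols[[cn]], table_name, cn)
  }
  tb
}

coerce_cdm_column <- function(x, type, table_name, col_name) {
  bad <- function(n) {
    abort(sprintf("Column %s.%s: %d value(s) not parseable as %s",
                  table_name, col_name, n, type))
  }
  switch(type,
    character = {
      x <- as.character(x)
      x[!is.na(x) & !nzchar(x)] <- NA_character_
      x
    },
    numeric = {
      if (is.numeric(x)) return(as.numeric(x))
      out <- suppressWarnings(as.numeric(x))
      n <- sum(is.na(out) & !is.na(x))
      if (n) bad(n)
      out
    },
    integer = {
      if (is.integer(x)) return(x)
      out <- suppressWarnings(as.integer(as.numeric(x)))
      n <- sum(is.na(out) & !is.na(x))
      if (n) bad(n)
      out
    },
    date = {
      if (inherits(x, "Date")) return(x)
      x <- as.character(x)
      x <- sub("[T ].*$", "", x)  # drop optional time part
      out <- as.Date(x, format = "%Y-%m-%d")
      n <- sum(is.na(out) & !is.na(x))
      if (n) bad(n)
      out
    },
    abort(paste0("Unknown schema type: ", type))
  )
}

#' Write a source table set as one CSV per table
#'
#' The inverse of [load_source()]: loading the written directory again
#' yields an identical `source_table_set`.
#'
#' @param sts A `source_table_set`.
#' @param dir_path Output directory (created if needed).
#' @return `dir_path`, invisibly.
#' @export
write_source_csv <- function(sts, dir_path) {
  stopifnot(inherits(sts, "source_table_set"))
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(sts$tables)) {
    tb <- sts$tables[[nm]]
    for (cn in names(tb)) {
      if (inherits(tb[[cn]], "Date")) tb[[cn]] <- format(tb[[cn]], "%Y-%m-%d")
    }
    readr::write_csv(tb, file.path(dir_path, paste0(nm, ".csv")), na = "",
                     progress = FALSE)
  }
  invisible(dir_path)
}

# -- validation ---------------------------------------------------------------

assert_unique <- function(x, what) {
  d <- unique(x[duplicated(x) & !is.na(x)])
  if (length(d)) {
    abort(paste0("Duplicate ", what, ": ", paste(head(d, 10), collapse = ", ")))
  }
}

assert_keys_exist <- function(child, parent, what) {
  orphans <- setdiff(child[!is.na(child)], parent)
  if (length(orphans)) {
    abort(paste0("Referential integrity violation: ", what,
                 " with no parent row: ",
                 paste(head(orphans, 10), collapse = ", ")))
  }
}

validate_source_tables <- function(sts) {
  if (sts$model == "i2b2") validate_i2b2(sts) else validate_pcornet(sts)
  invisible(sts)
}

validate_i2b2 <- function(sts) {
  tb <- sts$tables
  ofc <- tb$OBSERVATION_FACT
  assert_unique(tb$PATIENT_DIMENSION$PATIENT_NUM, "PATIENT_DIMENSION.PATIENT_NUM")
  assert_unique(tb$VISIT_DIMENSION$ENCOUNTER_NUM, "VISIT_DIMENSION.ENCOUNTER_NUM")
  assert_unique(tb$CONCEPT_DIMENSION$CONCEPT_CD, "CONCEPT_DIMENSION.CONCEPT_CD")
  assert_unique(tb$PROVIDER_DIMENSION$PROVIDER_ID, "PROVIDER_DIMENSION.PROVIDER_ID")

  if (any(!is.na(ofc$INSTANCE_NUM) & ofc$INSTANCE_NUM < 1L)) {
    abort("OBSERVATION_FACT.INSTANCE_NUM must be >= 1")
  }
  bad_vt <- !is.na(ofc$VALTYPE_CD) & !ofc$VALTYPE_CD %in% c("N", "T")
  if (any(bad_vt)) {
    abort(paste0("OBSERVATION_FACT.VALTYPE_CD outside {N, T}: ",
                 paste(unique(ofc$VALTYPE_CD[bad_vt]), collapse = ", ")))
  }
  num <- !is.na(ofc$VALTYPE_CD) & ofc$VALTYPE_CD == "N" & !is.na(ofc$TVAL_CHAR)
  bad_tv <- num & !ofc$TVAL_CHAR %in% c("E", "L", "G", "LE", "GE")
  if (any(bad_tv)) {
    abort(paste0("OBSERVATION_FACT.TVAL_CHAR for numeric facts must be a ",
                 "comparator flag (E, L, G, LE, GE); found: ",
                 paste(unique(ofc$TVAL_CHAR[bad_tv]), collapse = ", ")))
  }
  vd <- tb$VISIT_DIMENSION
  both <- !is.na(vd$START_DATE) & !is.na(vd$END_DATE)
  if (any(both & vd$START_DATE > vd$END_DATE)) {
    abort("VISIT_DIMENSION: START_DATE after END_DATE")
  }
  pats <- tb$PATIENT_DIMENSION$PATIENT_NUM
  assert_keys_exist(ofc$PATIENT_NUM, pats, "OBSERVATION_FACT.PATIENT_NUM")
  assert_keys_exist(vd$PATIENT_NUM, pats, "VISIT_DIMENSION.PATIENT_NUM")
  # OBSERVATION_FACT.ENCOUNTER_NUM may dangle: facts without a visit row are
  # dropped by the inner join in the labs view, so flag, don't fail.
  dangling <- setdiff(ofc$ENCOUNTER_NUM[!is.na(ofc$ENCOUNTER_NUM)],
                      vd$ENCOUNTER_NUM)
  if (length(dangling)) {
    warn(paste0(length(dangling), " OBSERVATION_FACT encounter id(s) have no ",
                "VISIT_DIMENSION row; their facts will be dropped by ",
                "visit-joined views"))
  }
}

validate_pcornet <- function(sts) {
  tb <- sts$tables
  assert_unique(tb$DEMOGRAPHIC$PATID, "DEMOGRAPHIC.PATID")
  assert_unique(tb$ENCOUNTER$ENCOUNTERID, "ENCOUNTER.ENCOUNTERID")
  assert_unique(tb$LAB_RESULT_CM$LAB_RESULT_CM_ID, "LAB_RESULT_CM.LAB_RESULT_CM_ID")
  assert_unique(tb$PROVIDER$PROVIDERID, "PROVIDER.PROVIDERID")

  pats <- tb$DEMOGRAPHIC$PATID
  encs <- tb$ENCOUNTER$ENCOUNTERID
  for (nm in c("ENCOUNTER", "DIAGNOSIS", "PROCEDURES", "VITAL",
               "LAB_RESULT_CM", "PRESCRIBING")) {
    assert_keys_exist(tb[[nm]]$PATID, pats, paste0(nm, ".PATID"))
    if (nm != "ENCOUNTER") {
      assert_keys_exist(tb[[nm]]$ENCOUNTERID, encs, paste0(nm, ".ENCOUNTERID"))
    }
  }
  lab <- tb$LAB_RESULT_CM
  mods <- c("EQ", "GE", "GT", "LE", "LT", "TX", "NI", "UN", "OT")
  bad <- !is.na(lab$RESULT_MODIFIER) & !lab$RESULT_MODIFIER %in% mods
  if (any(bad)) {
    abort(paste0("LAB_RESULT_CM.RESULT_MODIFIER outside the declared set: ",
                 paste(unique(lab$RESULT_MODIFIER[bad]), collapse = ", ")))
  }
  enc <- tb$ENCOUNTER
  both <- !is.na(enc$ADMIT_DATE) & !is.na(enc$DISCHARGE_DATE)
  if (any(both & enc$ADMIT_DATE > enc$DISCHARGE_DATE)) {
    abort("ENCOUNTER: ADMIT_DATE after DISCHARGE_DATE")
  }
}
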