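# The summary-statistics validation protocol: flatten both the FHIR output
# and a source-of-truth extract to per-variable records, summarize each
# variable (patient counts, mean, sd, quartiles for numerics; level counts
# for categoricals), and compare field by field. The source extract keeps
# untranslatable local codes as-is, so mapping losses surface as level-count
# mismatches rather than silently disappearing on both sides.

new_extract <- function(patient_id = character(), variable = character(),
                        type = character(), value_num = numeric(),
                        value_chr = character()) {
  tibble(patient_id = patient_id, variable = variable, type = type,
         value_num = value_num, value_chr = value_chr)
}

extract_rows_numeric <- function(patient_id, variable, values) {
  keep <- !is.na(values)
  new_extract(patient_id[keep], variable[keep], rep("numeric", sum(keep)),
              values[keep], rep(NA_character_, sum(keep)))
}

extract_rows_categorical <- function(patient_id, variable, values,
                                     keep = NULL) {
  keep <- keep %||% rep(TRUE, length(values))
  new_extract(patient_id[keep], variable[keep],
              rep("categorical", sum(keep)), rep(NA_real_, sum(keep)),
              as.character(values[keep]))
}

subject_patient_id <- function(res) {
  ref <- res$subject$reference %||% NA_character_
  sub("^Patient/", "", ref)
}

#' Flatten serialized FHIR output to a per-variable extract
#'
#' Reads the NDJSON files of one pipeline run and produces the long
#' per-patient extract the validation protocol summarizes: demographics
#' (`gender`, `race`, `ethnicity`), one numeric series per observation code
#' (`lab_<code>`, includes vitals), qualitative lab results
#' (`labtext_<code>`), smoking status, diagnosis and medication presence
#' records (`dx_<code>`, `med_<code>`), and encounter class.
#'
#' @param out_dir Directory holding the NDJSON output.
#' @return Extract tibble with columns `patient_id`, `variable`, `type`,
#'   `value_num`, `value_chr`.
#' @export
flatten_fhir <- function(out_dir) {
  sets <- read_fhir_ndjson(out_dir)
  out <- list()
  for (res in sets$patient %||% list()) {
    pid <- res$id
    ext_code <- function(url) {
      for (e in res$extension %||% list()) {
        if (identical(e$url, url)) {
          return(e$extension[[1]]$valueCoding$code %||% NA_character_)
        }
      }
      NA_character_
    }
    out[[length(out) + 1L]] <- new_extract(
      rep(pid, 3), c("gender", "race", "ethnicity"), rep("categorical", 3),
      rep(NA_real_, 3),
      c(res$gender %||% NA_character_,
        ext_code("http://hl7.org/fhir/us/core/StructureDefinition/us-core-race"),
        ext_code("http://hl7.org/fhir/us/core/StructureDefinition/us-core-ethnicity")))
  }
  for (res in sets$encounter %||% list()) {
    out[[length(out) + 1L]] <- new_extract(
      subject_patient_id(res), "encounter_class", "categorical", NA_real_,
      res$class$code %||% NA_character_)
  }
  obs_sets <- c(sets$observation_labs %||% list(),
                sets$observation_vitals %||% list(),
                sets$observation %||% list())
  for (res in obs_sets) {
    pid <- subject_patient_id(res)
    code <- res$code$coding[[1]]$code %||% NA_character_
    if (identical(code, vitals_loinc$smoking$code)) {
      out[[length(out) + 1L]] <- new_extract(
        pid, "smoking", "categorical", NA_real_,
        res$valueCodeableConcept$coding[[1]]$code %||% NA_character_)
    } else if (!is.null(res$valueQuantity)) {
      out[[length(out) + 1L]] <- new_extract(
        pid, paste0("lab_", code), "numeric",
        res$valueQuantity$value, NA_character_)
    } else if (!is.null(res$valueString)) {
      out[[length(out) + 1L]] <- new_extract(
        pid, paste0("labtext_", code), "categorical", NA_real_,
        res$valueString)
    }
  }
  for (res in sets$condition %||% list()) {
    code <- res$code$coding[[1]]$code %||% NA_character_
    out[[length(out) + 1L]] <- new_extract(
      subject_patient_id(res), paste0("dx_", code), "categorical",
      NA_real_, code)
  }
  for (res in sets$medicationrequest %||% list()) {
    code <- res$medicationCodeableConcept$coding[[1]]$code %||% NA_character_
    out[[length(out) + 1L]] <- new_extract(
      subject_patient_id(res), paste0("med_", code), "categorical",
      NA_real_, code)
  }
  list_rbind(c(list(new_extract()), unname(out)))
}

translate_or_keep <- function(xw, table_cd, column_cd, local) {
  mapped <- lookup_codes(xw, table_cd, column_cd, local)
  dplyr::coalesce(mapped, local)
}

#' Flatten a source table set to the same per-variable extract
#'
#' The source-of-truth side of the validation protocol. Coded variables are
#' translated through the crosswalk where a mapping exists; untranslatable
#' local codes are kept verbatim (not nulled), so a lossy mapping shows up
#' as a mismatch against the FHIR-derived extract instead of vanishing from
#' both sides. i2b2 fact rows are deduplicated and code prefixes stripped
#' so both models describe an identical event in identical terms.
#'
#' @param sts A `source_table_set`.
#' @param xw A `fhir_crosswalk`.
#' @param med_code_map Optional named character vector translating local
#'   medication ids to the code system used in the FHIR output (the
#'   crosswalk hook for sites whose source codes medications differently).
#' @return Extract tibble as in [flatten_fhir()].
#' @export
flatten_source <- function(sts, xw, med_code_map = NULL) {
  stopifnot(inherits(sts, "source_table_set"))
  out <- list()
  if (sts$model == "pcornet") {
    dem <- sts$tables$DEMOGRAPHIC
    out$gender <- extract_rows_categorical(
      dem$PATID, rep("gender", nrow(dem)),
      translate_or_keep(xw, "DEMOGRAPHIC", "SEX", dem$SEX))
    out$race <- extract_rows_categorical(
      dem$PATID, rep("race", nrow(dem)),
      translate_or_keep(xw, "DEMOGRAPHIC", "RACE", dem$RACE))
    out$ethnicity <- extract_rows_categorical(
      dem$PATID, rep("ethnicity", nrow(dem)),
      translate_or_keep(xw, "DEMOGRAPHIC", "HISPANIC", dem$HISPANIC))
    enc <- sts$tables$ENCOUNTER
    out$enc <- extract_rows_categorical(
      enc$PATID, rep("encounter_class", nrow(enc)),
      translate_or_keep(xw, "ENCOUNTER", "ENC_TYPE", enc$ENC_TYPE))
    lab <- sts$tables$LAB_RESULT_CM
    out$labs <- extract_rows_numeric(
      lab$PATID, paste0("lab_", lab$LAB_LOINC), lab$RESULT_NUM)
    qual <- lab$RESULT_QUAL
    qual[!is.na(qual) & qual == "NI"] <- NA_character_
    qual <- dplyr::coalesce(qual, lab$RAW_RESULT)
    out$labtext <- extract_rows_categorical(
      lab$PATID, paste0("labtext_", lab$LAB_LOINC), qual, keep = !is.na(qual))
    vit <- sts$tables$VITAL
    out$ht <- extract_rows_numeric(
      vit$PATID, rep(paste0("lab_", vitals_loinc$height$code), nrow(vit)),
      vit$HT)
    out$wt <- extract_rows_numeric(
      vit$PATID, rep(paste0("lab_", vitals_loinc$weight$code), nrow(vit)),
      vit$WT)
    out$smoking <- extract_rows_categorical(
      vit$PATID, rep("smoking", nrow(vit)),
      translate_or_keep(xw, "VITAL", "SMOKING", vit$SMOKING),
      keep = !is.na(vit$SMOKING))
    dx <- sts$tables$DIAGNOSIS
    out$dx <- extract_rows_categorical(
      dx$PATID, paste0("dx_", dx$DX), dx$DX, keep = !is.na(dx$DX))
    rx <- sts$tables$PRESCRIBING
    med <- rx$RXNORM_CUI
    if (!is.null(med_code_map)) {
      med <- dplyr::coalesce(unname(med_code_map[med]), med)
    }
    out$med <- extract_rows_categorical(
      rx$PATID, paste0("med_", med), med, keep = !is.na(med))
  } else {
    pd <- sts$tables$PATIENT_DIMENSION
    out$gender <- extract_rows_categorical(
      pd$PATIENT_NUM, rep("gender", nrow(pd)),
      translate_or_keep(xw, "PATIENT_DIMENSION", "SEX_CD", pd$SEX_CD))
    out$race <- extract_rows_categorical(
      pd$PATIENT_NUM, rep("race", nrow(pd)),
      translate_or_keep(xw, "PATIENT_DIMENSION", "RACE_CD", pd$RACE_CD))
    out$ethnicity <- extract_rows_categorical(
      pd$PATIENT_NUM, rep("ethnicity", nrow(pd)),
      translate_or_keep(xw, "PATIENT_DIMENSION", "ETHNICITY_CD",
                        pd$ETHNICITY_CD))
    vd <- sts$tables$VISIT_DIMENSION
    out$enc <- extract_rows_categorical(
      vd$PATIENT_NUM, rep("encounter_class", nrow(vd)),
      translate_or_keep(xw, "VISIT_DIMENSION", "INOUT_CD", vd$INOUT_CD))
    ofc <- distinct(sts$tables$OBSERVATION_FACT)
    is_lab <- !is.na(ofc$CONCEPT_CD) & startsWith(ofc$CONCEPT_CD, "LOINC")
    labs <- ofc[is_lab, , drop = FALSE]
    code <- strip_code_prefix(labs$CONCEPT_CD)
    num <- !is.na(labs$VALTYPE_CD) & labs$VALTYPE_CD == "N"
    out$labs <- extract_rows_numeric(
      labs$PATIENT_NUM[num], paste0("lab_", code[num]), labs$NVAL_NUM[num])
    txt <- !is.na(labs$VALTYPE_CD) & labs$VALTYPE_CD == "T"
    out$labtext <- extract_rows_categorical(
      labs$PATIENT_NUM[txt], paste0("labtext_", code[txt]),
      labs$TVAL_CHAR[txt])
    vit <- ofc[!is.na(ofc$CONCEPT_CD) &
                 startsWith(ofc$CONCEPT_CD, "VITAL:"), , drop = FALSE]
    vcode <- sub("^VITAL:", "", vit$CONCEPT_CD)
    out$ht <- extract_rows_numeric(
      vit$PATIENT_NUM[vcode == "HT"],
      rep(paste0("lab_", vitals_loinc$height$code), sum(vcode == "HT")),
      vit$NVAL_NUM[vcode == "HT"])
    out$wt <- extract_rows_numeric(
      vit$PATIENT_NUM[vcode == "WT"],
      rep(paste0("lab_", vitals_loinc$weight$code), sum(vcode == "WT")),
      vit$NVAL_NUM[vcode == "WT"])
    sm <- vcode == "SMOKING"
    out$smoking <- extract_rows_categorical(
      vit$PATIENT_NUM[sm], rep("smoking", sum(sm)),
      translate_or_keep(xw, "OBSERVATION_FACT", "SMOKING_CD",
                        vit$TVAL_CHAR[sm]))
    dx <- ofc[!is.na(ofc$CONCEPT_CD) &
                startsWith(ofc$CONCEPT_CD, "ICD10"), , drop = FALSE]
    dcode <- strip_code_prefix(dx$CONCEPT_CD)
    out$dx <- extract_rows_categorical(
      dx$PATIENT_NUM, paste0("dx_", dcode), dcode)
    rx <- ofc[!is.na(ofc$CONCEPT_CD) &
                startsWith(ofc$CONCEPT_CD, "RXNORM"), , drop = FALSE]
    mcode <- strip_code_prefix(rx$CONCEPT_CD)
    if (!is.null(med_code_map)) {
      mcode <- dplyr::coalesce(unname(med_code_map[mcode]), mcode)
    }
    out$med <- extract_rows_categorical(
      rx$PATIENT_NUM, paste0("med_", mcode), mcode)
  }
  list_rbind(c(list(new_extract()), unname(out)))
}

#' Summarize a per-variable extract
#'
#' Numeric variables get patient and record counts, mean, sample standard
#' deviation (reported as `NA` below two records) and linearly interpolated
#' quartiles; categorical variables get patient counts and level counts
#' (missing values counted under `"(missing)"` so that mapped-to-null
#' losses stay visible).
#'
#' @param extract Tibble from [flatten_fhir()] or [flatten_source()].
#' @return Tibble with one row per variable: `variable`, `type`,
#'   `n_patients`, `n`, `mean`, `sd`, `q1`, `median`, `q3`, `levels`
#'   (list-column of named counts).
#' @export
#' @examples
#' ex <- tibble::tibble(patient_id = c("1", "2"), variable = "lab_x",
#'                      type = "numeric", value_num = c(1, 3),
#'                      value_chr = NA_character_)
#' summarize_extract(ex)$mean
summarize_extract <- function(extract) {
  if (nrow(extract) == 0L) {
    return(tibble(variable = character(), type = character(),
                  n_patients = integer(), n = integer(), mean = numeric(),
                  sd = numeric(), q1 = numeric(), median = numeric(),
                  q3 = numeric(), levels = list()))
  }
  extract |>
    group_by(.data$variable, .data$type) |>
    summarise(
      n_patients = dplyr::n_distinct(.data$patient_id),
      n = dplyr::n(),
      mean = if (.data$type[1] == "numeric") mean(.data$value_num) else NA_real_,
      sd = if (.data$type[1] == "numeric" && dplyr::n() > 1L)
        stats::sd(.data$value_num) else NA_real_,
      q1 = if (.data$type[1] == "numeric")
        unname(stats::quantile(.data$value_num, 0.25, type = 7)) else NA_real_,
      median = if (.data$type[1] == "numeric")
        unname(stats::median(.data$value_num)) else NA_real_,
      q3 = if (.data$type[1] == "numeric")
        unname(stats::quantile(.data$value_num, 0.75, type = 7)) else NA_real_,
      levels = list(if (.data$type[1] == "categorical") {
        v <- .data$value_chr
        v[is.na(v)] <- "(missing)"
        tab <- table(v)
        setNames(as.integer(tab), names(tab))
      } else NULL),
      .groups = "drop"
    ) |>
    arrange(.data$variable)
}

num_match <- function(a, b, tol) {
  if (is.na(a) && is.na(b)) return(TRUE)
  if (is.na(a) || is.na(b)) return(FALSE)
  abs(a - b) <= tol * max(1, abs(a), abs(b))
}

#' Compare two variable summaries
#'
#' Field-by-field comparison of a source summary against a FHIR-derived
#' summary: numeric statistics must agree within `tolerance` (relative,
#' near-exact by default), categorical level counts must agree exactly, and
#' a variable present on only one side is a mismatch. The verdict is
#' symmetric in the arguments.
#'
#' @param source_summary,fhir_summary Tibbles from [summarize_extract()].
#' @param tolerance Relative numeric tolerance (default `1e-9`).
#' @return A `validation_report`: per-variable match flags, a mismatch
#'   table carrying both values, and `match_percentage` in `[0, 100]`
#'   (100 exactly when there are no mismatches).
#' @export
compare_summaries <- function(source_summary, fhir_summary,
                              tolerance = 1e-9) {
  vars <- sort(union(source_summary$variable, fhir_summary$variable))
  num_fields <- c("n_patients", "n", "mean", "sd", "q1", "median", "q3")
  rows <- list(); mism <- list()
  for (v in vars) {
    a <- source_summary[source_summary$variable == v, ]
    b <- fhir_summary[fhir_summary$variable == v, ]
    fields_bad <- character()
    if (nrow(a) == 0L || nrow(b) == 0L) {
      fields_bad <- "presence"
      mism[[length(mism) + 1L]] <- tibble(
        variable = v, field = "presence",
        source = if (nrow(a)) "present" else "absent",
        fhir = if (nrow(b)) "present" else "absent")
    } else {
      for (f in num_fields) {
        if (!num_match(a[[f]], b[[f]], tolerance)) {
          fields_bad <- c(fields_bad, f)
          mism[[length(mism) + 1L]] <- tibble(
            variable = v, field = f,
            source = format(a[[f]]), fhir = format(b[[f]]))
        }
      }
      la <- a$levels[[1]]; lb <- b$levels[[1]]
      if (!identical(la, lb)) {
        fields_bad <- c(fields_bad, "levels")
        fmt <- function(x) if (is.null(x)) "NULL"
          else paste(names(x), x, sep = "=", collapse = ", ")
        mism[[length(mism) + 1L]] <- tibble(
          variable = v, field = "levels", source = fmt(la), fhir = fmt(lb))
      }
    }
    rows[[length(rows) + 1L]] <- tibble(
      variable = v, match = length(fields_bad) == 0L,
      fields = paste(fields_bad, collapse = ","))
  }
  comparison <- bind_rows(rows)
  mismatches <- if (length(mism)) bind_rows(mism) else
    tibble(variable = character(), field = character(),
           source = character(), fhir = character())
  structure(list(
    comparison = comparison,
    mismatches = mismatches,
    n_variables = length(vars),
    match_percentage = if (length(vars)) 100 * mean(comparison$match) else 100
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d variables, %.1f%% matched\n",
              x$n_variables, x$match_percentage))
  if (nrow(x$mismatches)) {
    cat(" mismatches:\n")
    print(x$mismatches, n = 20)
  }
  invisible(x)
}

#' @rdname compare_summaries
#' @param x A `validation_report`.
#' @param ... Unused.
#' @export
tidy.validation_report <- function(x, ...) x$comparison

#' @rdname compare_summaries
#' @export
glance.validation_report <- function(x, ...) {
  tibble(n_variables = x$n_variables,
         n_mismatches = sum(!x$comparison$match),
         match_percentage = x$match_percentage)
}

#' Plot match status by variable group
#'
#' @param object A `validation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.validation_report <- function(object, ...) {
  tb <- object$comparison |>
    mutate(group = sub("_.*$", "", .data$variable)) |>
    count(.data$group, .data$match)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$group, y = .data$n,
                                   fill = .data$match)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "seagreen",
                                          `FALSE` = "firebrick")) +
    ggplot2::labs(x = "variable group", y = "variables",
                  fill = "matched",
                  title = "Source vs FHIR summary-statistics comparison") +
    ggplot2::theme_minimal()
}
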