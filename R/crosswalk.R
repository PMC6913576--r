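#' Load a value-set crosswalk
#'
#' Reads the single-table crosswalk that drives all local-code to FHIR-code
#' translation. The file must carry the five columns
#' `TABLE_CD, COLUMN_CD, LOCAL_IN_CD, FHIR_OUT_CD, FHIR_SYSTEM`; the key
#' `(TABLE_CD, COLUMN_CD, LOCAL_IN_CD)` must be unique. Local codes are
#' matched case-sensitively after whitespace trimming. An entry whose
#' `FHIR_OUT_CD` is not a member of the bundled reference value set for its
#' system is kept but flagged with a warning.
#'
#' Two starter crosswalks ship with the package, see
#' [starter_crosswalk_path()].
#'
#' @param path Path to the crosswalk CSV.
#' @return A `fhir_crosswalk` object supporting [lookup_code()].
#' @export
#' @examples
#' xw <- load_crosswalk(starter_crosswalk_path("i2b2"))
#' lookup_code(xw, "VISIT_DIMENSION", "INOUT_CD", "EMERGENCY")
load_crosswalk <- function(path) {
  raw <- readr::read_csv(
    path, col_types = readr::cols(.default = readr::col_character()),
    na = c(""), progress = FALSE, show_col_types = FALSE
  )
  names(raw) <- toupper(names(raw))
  wanted <- c("TABLE_CD", "COLUMN_CD", "LOCAL_IN_CD", "FHIR_OUT_CD",
              "FHIR_SYSTEM")
  if (!setequal(names(raw), wanted)) {
    abort(paste0("Crosswalk must have exactly the columns ",
                 paste(wanted, collapse = ", ")))
  }
  entries <- as_tibble(raw)[wanted]
  for (cn in names(entries)) entries[[cn]] <- trimws(entries[[cn]])
  bad <- !is.na(entries$FHIR_OUT_CD) & is.na(entries$FHIR_SYSTEM)
  if (any(bad)) {
    abort("Crosswalk rows with FHIR_OUT_CD but no FHIR_SYSTEM")
  }
  key <- paste(entries$TABLE_CD, entries$COLUMN_CD, entries$LOCAL_IN_CD,
               sep = "\r")
  dup <- unique(key[duplicated(key)])
  if (length(dup)) {
    abort(paste0("Duplicate crosswalk key(s): ",
                 paste(gsub("\r", "/", head(dup, 5)), collapse = "; ")))
  }
  for (i in seq_len(nrow(entries))) {
    code <- entries$FHIR_OUT_CD[i]
    if (is.na(code)) next
    known <- system_codes(entries$FHIR_SYSTEM[i])
    if (!is.null(known) && !code %in% known) {
      warn(paste0("Crosswalk FHIR_OUT_CD '", code,
                  "' is not in the bundled value set for system '",
                  entries$FHIR_SYSTEM[i], "' (entry kept)"))
    }
  }
  index <- new.env(parent = emptyenv(), size = max(16L, nrow(entries)))
  for (i in seq_len(nrow(entries))) {
    assign(key[i], list(code = entries$FHIR_OUT_CD[i],
                        system = entries$FHIR_SYSTEM[i]),
           envir = index)
  }
  structure(
    list(entries = entries, index = index,
         misses = new.env(parent = emptyenv())),
    class = "fhir_crosswalk"
  )
}

#' An empty crosswalk (every lookup misses)
#' @return A `fhir_crosswalk` with no entries.
#' @export
empty_crosswalk <- function() {
  tmp <- tempfile(fileext = ".csv")
  writeLines("TABLE_CD,COLUMN_CD,LOCAL_IN_CD,FHIR_OUT_CD,FHIR_SYSTEM", tmp)
  on.exit(unlink(tmp))
  load_crosswalk(tmp)
}

#' Path of a bundled starter crosswalk
#'
#' @param model `"i2b2"` or `"pcornet"`.
#' @return Path to the shipped crosswalk CSV for that source model.
#' @export
starter_crosswalk_path <- function(model) {
  model <- match.arg(model, c("i2b2", "pcornet"))
  system.file("extdata", paste0(model, "_crosswalk.csv"),
              package = "cdm2fhir", mustWork = TRUE)
}

#' Translate one local code to its FHIR code and system
#'
#' Exact-match lookup on `(table, column, local code)` after whitespace
#' trimming; a miss returns `NULL` and never raises. The PCORnet sentinels
#' `NI`/`UN`/`OT` therefore translate to null unless an explicit crosswalk
#' row says otherwise. Misses are tallied per `(table, column)`; see
#' [crosswalk_misses()].
#'
#' @param xw A `fhir_crosswalk`.
#' @param table_cd,column_cd Source table and column name.
#' @param local_code Local code to translate.
#' @return `list(code =, system =)` or `NULL` on a miss (also when
#'   `local_code` is missing).
#' @export
lookup_code <- function(xw, table_cd, column_cd, local_code) {
  stopifnot(inherits(xw, "fhir_crosswalk"))
  if (is.null(local_code) || is.na(local_code)) return(NULL)
  key <- paste(trimws(table_cd), trimws(column_cd), trimws(local_code),
               sep = "\r")
  hit <- get0(key, envir = xw$index, inherits = FALSE)
  if (is.null(hit) || is.na(hit$code)) {
    tally_miss(xw, table_cd, column_cd)
    return(NULL)
  }
  hit
}

# vectorized translation used by the view builders: returns the FHIR codes
# (NA on miss) for a vector of local codes.
lookup_codes <- function(xw, table_cd, column_cd, local_codes) {
  vapply(local_codes, function(cd) {
    hit <- lookup_code(xw, table_cd, column_cd, cd)
    if (is.null(hit)) NA_character_ else hit$code
  }, character(1), USE.NAMES = FALSE)
}

lookup_systems <- function(xw, table_cd, column_cd, local_codes) {
  vapply(local_codes, function(cd) {
    hit <- lookup_code(xw, table_cd, column_cd, cd)
    if (is.null(hit)) NA_character_ else hit$system
  }, character(1), USE.NAMES = FALSE)
}

tally_miss <- function(xw, table_cd, column_cd) {
  key <- paste(table_cd, column_cd, sep = ".")
  cur <- get0(key, envir = xw$misses, inherits = FALSE) %||% 0L
  assign(key, cur + 1L, envir = xw$misses)
  invisible(NULL)
}

#' Crosswalk miss tally
#'
#' Unmappable local codes are left null in the FHIR output; that loss can be
#' significant, so every miss is counted per source `(table, column)`.
#'
#' @param xw A `fhir_crosswalk`.
#' @return Tibble with columns `table_cd`, `column_cd`, `misses`.
#' @export
crosswalk_misses <- function(xw) {
  keys <- ls(xw$misses)
  if (!length(keys)) {
    return(tibble(table_cd = character(), column_cd = character(),
                  misses = integer()))
  }
  parts <- strsplit(keys, ".", fixed = TRUE)
  tibble(
    table_cd = map_chr(parts, 1),
    column_cd = map_chr(parts, function(p) paste(p[-1], collapse = ".")),
    misses = map_int(keys, function(k) get(k, envir = xw$misses))
  ) |> arrange(.data$table_cd, .data$column_cd)
}

reset_misses <- function(xw) {
  rm(list = ls(xw$misses), envir = xw$misses)
  invisible(xw)
}

#' @export
print.fhir_crosswalk <- function(x, ...) {
  cat("<fhir_crosswalk>", nrow(x$entries), "entries\n")
  print(count(x$entries, .data$TABLE_CD, .data$COLUMN_CD), n = 20)
  invisible(x)
}
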