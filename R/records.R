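#' Default column mapping for discharge-record tables
#'
#' Hospital discharge extracts differ in layout, so the reader is driven by
#' a configuration that names the columns holding each canonical field.
#' Diagnoses may live in a single delimited cell (`diagnoses` +
#' `diagnosis_sep`) or in wide columns `diag1...diagK` (`wide_prefix`).
#'
#' @param path optional YAML file overriding the defaults; its keys mirror
#'   the returned list.
#' @return list with elements `columns` (named list patient_id, sex,
#'   age_years, discharge_date, department, diagnoses), `diagnosis_sep`,
#'   `wide_prefix`.
#' @export
record_config <- function(path = NULL) {
  config <- list(
    columns = list(
      patient_id = "patient_id",
      sex = "sex",
      age_years = "age_years",
      discharge_date = "discharge_date",
      department = "department",
      diagnoses = "diagnoses"
    ),
    diagnosis_sep = ";",
    wide_prefix = NULL
  )
  if (!is.null(path)) {
    if (!file.exists(path)) stop_config(sprintf("config file not found: %s", path))
    user <- yaml::read_yaml(path)
    for (key in names(user)) {
      if (key == "columns") {
        config$columns[names(user$columns)] <- user$columns
      } else {
        config[[key]] <- user[[key]]
      }
    }
  }
  config
}

.normalize_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("male", "m", "1")] <- "male"
  out[x %in% c("female", "f", "2")] <- "female"
  out
}

new_discharge_records <- function(df) {
  stopifnot(is.list(df$diagnoses))
  class(df) <- c("discharge_records", "data.frame")
  df
}

#' Read and validate a discharge-record table
#'
#' Each row is one hospitalization: patient id, sex, age at discharge,
#' discharge date, department, and an ordered diagnosis list (first =
#' primary diagnosis). Rows failing validation (bad code, age outside
#' 0--130, unknown sex, empty diagnosis list) are collected with their row
#' numbers; in the default lenient mode they are dropped with a warning and
#' reported in the `problems` attribute, in strict mode they abort.
#'
#' @param path CSV/TSV file (UTF-8).
#' @param config column mapping from [record_config()].
#' @param strict abort on the first invalid row instead of dropping it.
#' @param sep field separator passed to [utils::read.csv()].
#' @return a `discharge_records` data frame with list-column `diagnoses`;
#'   attribute `problems` holds a data frame (row, field, message).
#' @export
read_records <- function(path, config = record_config(), strict = FALSE,
                         sep = ",") {
  if (!file.exists(path)) stop_config(sprintf("input file not found: %s", path))
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0L) {
    warning("no records in ", path)
    return(new_discharge_records(data.frame(
      patient_id = character(), sex = character(), age_years = integer(),
      discharge_date = as.Date(character()), department = character(),
      diagnoses = I(list()), stringsAsFactors = FALSE
    )))
  }
  cols <- config$columns
  needed <- unlist(cols[c("patient_id", "sex", "age_years", "discharge_date",
                          "department")])
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0L) {
    stop_config(sprintf("missing mandatory column(s): %s",
                        paste(missing, collapse = ", ")))
  }

  if (!is.null(config$wide_prefix)) {
    diag_cols <- grep(paste0("^", config$wide_prefix, "[0-9]+$"), names(raw),
                      value = TRUE)
    if (length(diag_cols) == 0L) {
      stop_config(sprintf("no '%s<k>' diagnosis columns found", config$wide_prefix))
    }
    diag_cols <- diag_cols[order(as.integer(sub(config$wide_prefix, "", diag_cols)))]
    diagnoses <- lapply(seq_len(nrow(raw)), function(i) {
      v <- trimws(unlist(raw[i, diag_cols], use.names = FALSE))
      v[!is.na(v) & nzchar(v)]
    })
  } else {
    if (!cols$diagnoses %in% names(raw)) {
      stop_config(sprintf("missing mandatory column(s): %s", cols$diagnoses))
    }
    diagnoses <- strsplit(raw[[cols$diagnoses]], config$diagnosis_sep, fixed = TRUE)
    diagnoses <- lapply(diagnoses, function(v) {
      v <- trimws(v)
      v[!is.na(v) & nzchar(v)]
    })
  }

  records <- data.frame(
    patient_id = trimws(raw[[cols$patient_id]]),
    sex = .normalize_sex(raw[[cols$sex]]),
    age_years = suppressWarnings(as.integer(raw[[cols$age_years]])),
    discharge_date = as.Date(raw[[cols$discharge_date]]),
    department = trimws(raw[[cols$department]]),
    stringsAsFactors = FALSE
  )
  records$diagnoses <- diagnoses

  problems <- .validate_records(records)
  if (nrow(problems) > 0L) {
    if (strict) {
      stop_validation(sprintf("%d invalid record row(s); first: row %d, %s",
                              length(unique(problems$row)), problems$row[1],
                              problems$message[1]),
                      problems = problems)
    }
    bad <- unique(problems$row)
    warning(sprintf("dropping %d invalid record row(s); see attr(.,'problems')",
                    length(bad)))
    records <- records[-bad, , drop = FALSE]
    rownames(records) <- NULL
  }
  records <- new_discharge_records(records)
  attr(records, "problems") <- problems
  records
}

.validate_records <- function(records) {
  problems <- list()
  note <- function(row, field, message) {
    problems[[length(problems) + 1L]] <<- data.frame(
      row = row, field = field, message = message, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(records))) {
    if (is.na(records$patient_id[i]) || !nzchar(records$patient_id[i]))
      note(i, "patient_id", "empty patient id")
    if (is.na(records$sex[i]))
      note(i, "sex", "sex not one of male/female")
    age <- records$age_years[i]
    if (is.na(age) || age < 0L || age > 130L)
      note(i, "age_years", sprintf("age '%s' outside [0, 130]", age))
    if (is.na(records$discharge_date[i]))
      note(i, "discharge_date", "unparseable date")
    dx <- records$diagnoses[[i]]
    if (length(dx) == 0L) {
      note(i, "diagnoses", "empty diagnosis list")
    } else {
      if (length(dx) > 41L)
        note(i, "diagnoses", sprintf("%d diagnoses exceeds 1 primary + 40 secondary", length(dx)))
      bad <- dx[!is_icd10(dx)]
      if (length(bad) > 0L)
        note(i, "diagnoses", sprintf("malformed ICD-10 code(s): %s",
                                     paste(utils::head(bad, 3L), collapse = ", ")))
    }
  }
  if (length(problems) == 0L) {
    data.frame(row = integer(), field = character(), message = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, problems)
  }
}

#' Write discharge records in the canonical CSV layout
#'
#' The canonical layout joins the diagnosis list with ";" so that
#' `read_records()` round-trips all fields.
#'
#' @param records a `discharge_records` data frame.
#' @param path output file.
#' @export
write_records <- function(records, path) {
  out <- data.frame(
    patient_id = records$patient_id,
    sex = records$sex,
    age_years = records$age_years,
    discharge_date = format(records$discharge_date, "%Y-%m-%d"),
    department = records$department,
    diagnoses = vapply(records$diagnoses, paste, "", collapse = ";"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
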