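#' ICD-10 chapter boundaries
#'
#' Static table mapping three-character ICD-10 categories to the standard
#' chapters I--XXII. U codes (chapter XXII, codes for special purposes) are
#' carried like the injury/external-cause/health-contact chapters XIX--XXI
#' and are excluded from comorbidity analysis downstream by default.
#'
#' @format A data frame with columns `chapter` (roman numeral), `from`,
#'   `to` (inclusive three-character code bounds).
#' @export
icd10_chapters <- function() {
  data.frame(
    chapter = c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX",
                "X", "XI", "XII", "XIII", "XIV", "XV", "XVI", "XVII",
                "XVIII", "XIX", "XIX", "XX", "XX", "XX", "XX", "XXI", "XXII"),
    from = c("A00", "C00", "D50", "E00", "F00", "G00", "H00", "H60", "I00",
             "J00", "K00", "L00", "M00", "N00", "O00", "P00", "Q00",
             "R00", "S00", "T00", "V01", "W00", "X00", "Y00", "Z00", "U00"),
    to   = c("B99", "D48", "D89", "E90", "F99", "G99", "H59", "H95", "I99",
             "J99", "K99", "L99", "M99", "N99", "O99", "P96", "Q99",
             "R99", "S99", "T98", "V99", "W99", "X99", "Y98", "Z99", "U85"),
    stringsAsFactors = FALSE
  )
}

# Pattern for a full ICD-10 code: letter + two digits, optional ".x" detail.
.icd10_pattern <- "^[A-Za-z][0-9]{2}(\\.[0-9A-Za-z]+)?$"

#' Test whether strings are well-formed ICD-10 codes
#'
#' @param code character vector of candidate codes.
#' @return logical vector.
#' @export
is_icd10 <- function(code) {
  !is.na(code) & grepl(.icd10_pattern, code)
}

#' Chapter of a three-character ICD-10 category
#'
#' @param code3 character vector of three-character categories (e.g. "I50").
#' @return character vector of roman-numeral chapters ("I".."XXII").
#' @export
icd10_chapter <- function(code3) {
  tab <- icd10_chapters()
  code3 <- toupper(code3)
  out <- rep(NA_character_, length(code3))
  for (i in seq_len(nrow(tab))) {
    hit <- code3 >= tab$from[i] & code3 <= tab$to[i]
    out[hit & is.na(out)] <- tab$chapter[i]
  }
  out
}

#' Truncate ICD-10 codes to their three-character category
#'
#' Comorbidity analysis works at the three-digit level: "I42.0" and "I42.9"
#' are the same chronic condition. Truncation uppercases and keeps the
#' first three characters, then attaches the chapter.
#'
#' @param code character vector of ICD-10 codes.
#' @param strict error on malformed codes (default) or return `NA` rows.
#' @return data frame with columns `code`, `code3`, `chapter`.
#' @export
#' @examples
#' truncate_code(c("I42.0", "e78", "S72.1"))
truncate_code <- function(code, strict = TRUE) {
  ok <- is_icd10(code)
  if (strict && any(!ok)) {
    stop_validation(sprintf(
      "malformed ICD-10 code(s): %s",
      paste(utils::head(code[!ok], 5L), collapse = ", ")
    ))
  }
  code3 <- ifelse(ok, toupper(substr(code, 1L, 3L)), NA_character_)
  data.frame(
    code = code,
    code3 = code3,
    chapter = icd10_chapter(code3),
    stringsAsFactors = FALSE
  )
}
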