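#' Default age strata
#'
#' The seven bands used for age-specific networks. Labels are serialized as
#' "0-19", "20-29", ..., "70+" in all outputs.
#'
#' @return data frame with columns `lo`, `hi` (inclusive), `label`.
#' @export
age_strata <- function() {
  data.frame(
    lo = c(0L, 20L, 30L, 40L, 50L, 60L, 70L),
    hi = c(19L, 29L, 39L, 49L, 59L, 69L, 130L),
    label = c("0-19", "20-29", "30-39", "40-49", "50-59", "60-69", "70+"),
    stringsAsFactors = FALSE
  )
}

.check_strata <- function(strata) {
  if (!all(c("lo", "hi", "label") %in% names(strata)))
    stop_config("strata must have columns lo, hi, label")
  s <- strata[order(strata$lo), , drop = FALSE]
  if (any(s$hi < s$lo)) stop_config("stratum with hi < lo")
  if (s$lo[1] > 0L || s$hi[nrow(s)] < 130L)
    stop_config("strata must cover ages 0 to 130")
  if (nrow(s) > 1L && any(s$lo[-1L] != s$hi[-nrow(s)] + 1L))
    stop_config("strata overlap or leave gaps: must partition [0, 130]")
  s
}

new_cohort_matrix <- function(incidence, group = "case", stratum = "all") {
  stopifnot(is.matrix(incidence), all(incidence %in% c(0L, 1L)))
  structure(
    list(
      group = group,
      stratum = stratum,
      incidence = incidence,
      n_patients = nrow(incidence),
      prevalence = if (ncol(incidence) > 0) colMeans(incidence) else numeric()
    ),
    class = "cohort_matrix"
  )
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf("cohort_matrix: %s / %s, %d patients x %d diseases\n",
              x$group, x$stratum, x$n_patients, ncol(x$incidence)))
  invisible(x)
}

#' Read a chronic-disease code list
#'
#' One three-character code per line; `#` starts a comment. The package
#' ships an editable example under `inst/extdata/chronic_codes.txt`.
#'
#' @param path file path.
#' @return character vector of code3 values.
#' @export
read_chronic_list <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("chronic list not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- toupper(trimws(lines))
  unique(lines[nzchar(lines)])
}

#' Identify chronic comorbidities as a binary incidence matrix
#'
#' Diagnosis codes are truncated to three characters, restricted to the
#' chronic-disease list (if given), stripped of the non-disease chapters
#' (injury/poisoning XIX, external causes XX, health-status contacts XXI,
#' and special-purpose U codes XXII by default), then unioned per patient
#' across all of that patient's hospitalizations (or kept per record in
#' record-level mode). Diseases whose prevalence does not exceed
#' `prevalence_floor` are dropped: the comorbidity universe is diseases
#' with prevalence strictly over the floor (default 1%).
#'
#' @param records a `discharge_records` data frame.
#' @param chronic_list optional character vector of code3 values to keep.
#' @param prevalence_floor retain diseases with prevalence > this fraction.
#' @param excluded_chapters roman-numeral chapters to drop.
#' @param level `"patient"` (union across a patient's records; default) or
#'   `"record"` (each hospitalization is a row/denominator unit).
#' @param group,stratum labels stored on the result.
#' @return a `cohort_matrix`.
#' @export
identify_comorbidities <- function(records, chronic_list = NULL,
                                   prevalence_floor = 0.01,
                                   excluded_chapters = c("XIX", "XX", "XXI", "XXII"),
                                   level = c("patient", "record"),
                                   group = "case", stratum = "all") {
  level <- match.arg(level)
  if (nrow(records) == 0L) stop_validation("no records supplied")
  if (prevalence_floor < 0 || prevalence_floor >= 1)
    stop_config("prevalence_floor must be in [0, 1)")

  unit <- if (level == "patient") records$patient_id else
    sprintf("rec%06d", seq_len(nrow(records)))
  codes <- lapply(records$diagnoses, function(dx) {
    tc <- truncate_code(dx, strict = FALSE)
    unique(tc$code3[!is.na(tc$code3) & !(tc$chapter %in% excluded_chapters)])
  })
  long <- data.frame(
    unit = rep(unit, lengths(codes)),
    code3 = unlist(codes),
    stringsAsFactors = FALSE
  )
  if (!is.null(chronic_list))
    long <- long[long$code3 %in% toupper(chronic_list), , drop = FALSE]
  units <- unique(unit)
  if (nrow(long) == 0L)
    stop_empty("no comorbidities retained after code filtering")

  diseases <- sort(unique(long$code3))
  incidence <- matrix(0L, nrow = length(units), ncol = length(diseases),
                      dimnames = list(units, diseases))
  incidence[cbind(match(long$unit, units), match(long$code3, diseases))] <- 1L

  keep <- colMeans(incidence) > prevalence_floor
  if (!any(keep))
    stop_empty(sprintf("no comorbidities retained above the %.3g prevalence floor",
                       prevalence_floor))
  new_cohort_matrix(incidence[, keep, drop = FALSE], group = group,
                    stratum = stratum)
}

#' Per-patient comorbid burden
#'
#' The comorbid burden is the number of distinct retained comorbidities a
#' patient accumulated over the study period (a row sum of the incidence
#' matrix).
#'
#' @param matrix a `cohort_matrix`.
#' @return list with `counts` (named integer vector), `mean_burden`, and
#'   `share_multimorbid` (fraction of patients with >= 2 comorbidities).
#' @export
comorbid_burden <- function(matrix) {
  stopifnot(inherits(matrix, "cohort_matrix"))
  counts <- rowSums(matrix$incidence)
  list(
    counts = counts,
    mean_burden = mean(counts),
    share_multimorbid = mean(counts >= 2)
  )
}

.first_record_index <- function(records) {
  ord <- order(records$patient_id, records$discharge_date)
  first <- !duplicated(records$patient_id[ord])
  ord[first]
}

#' Build one incidence matrix per age stratum
#'
#' Each patient is assigned to exactly one stratum by age at their first
#' (earliest) discharge; the prevalence floor is re-applied within each
#' stratum. Strata must partition the ages 0--130 (overlap or gaps are a
#' configuration error). Strata in which no comorbidity survives filtering
#' are returned as `NULL` with a warning.
#'
#' @inheritParams identify_comorbidities
#' @param strata data frame as returned by [age_strata()].
#' @param ... passed on to [identify_comorbidities()].
#' @return named list of `cohort_matrix` objects, one per stratum label.
#' @export
stratify_by_age <- function(records, strata = age_strata(), group = "case",
                            ...) {
  strata <- .check_strata(strata)
  first <- records[.first_record_index(records), , drop = FALSE]
  idx <- findInterval(first$age_years, c(strata$lo, 131L))
  stratum_of <- stats::setNames(strata$label[idx], first$patient_id)

  out <- stats::setNames(vector("list", nrow(strata)), strata$label)
  for (lab in strata$label) {
    ids <- names(stratum_of)[stratum_of == lab]
    sub <- records[records$patient_id %in% ids, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning(sprintf("stratum %s: no patients", lab))
      next
    }
    out[[lab]] <- tryCatch(
      identify_comorbidities(sub, group = group, stratum = lab, ...),
      pdnet_empty_result = function(e) {
        warning(sprintf("stratum %s: %s", lab, conditionMessage(e)))
        NULL
      }
    )
  }
  out
}

#' Match each case to one control by caliper matching
#'
#' Deterministic one-to-one matching without replacement: exact on sex and
#' department, birth year (discharge year minus age) within
#' `caliper_years`, and, among the eligible pool patients, the smallest
#' discharge-date distance. Cases are processed in patient-id order and
#' ties broken by pool patient id, so the matching is reproducible.
#' Matching operates on each patient's first record; all records of a
#' matched pool patient become that case's control records.
#'
#' @param cases,pool `discharge_records` data frames with disjoint patients.
#' @param caliper_years birth-year caliper (default 2).
#' @return list with `pairs` (case_id, control_id), `controls` (records of
#'   matched pool patients, a `discharge_records` frame), and `unmatched`
#'   (case patient ids without an eligible control).
#' @export
match_controls <- function(cases, pool, caliper_years = 2L) {
  if (nrow(pool) == 0L) stop_validation("control pool is empty")
  if (length(intersect(cases$patient_id, pool$patient_id)) > 0L)
    stop_config("case and pool patients overlap")

  cf <- cases[.first_record_index(cases), , drop = FALSE]
  pf <- pool[.first_record_index(pool), , drop = FALSE]
  cf <- cf[order(cf$patient_id), , drop = FALSE]
  pf <- pf[order(pf$patient_id), , drop = FALSE]
  birth <- function(df) as.integer(format(df$discharge_date, "%Y")) - df$age_years
  cf$birth_year <- birth(cf)
  pf$birth_year <- birth(pf)

  used <- rep(FALSE, nrow(pf))
  pairs <- vector("list", nrow(cf))
  for (i in seq_len(nrow(cf))) {
    ok <- !used &
      pf$sex == cf$sex[i] &
      pf$department == cf$department[i] &
      abs(pf$birth_year - cf$birth_year[i]) <= caliper_years
    if (!any(ok)) next
    gap <- abs(as.numeric(pf$discharge_date - cf$discharge_date[i]))
    gap[!ok] <- Inf
    j <- which.min(gap)  # pf is patient-id sorted, so ties resolve by id
    used[j] <- TRUE
    pairs[[i]] <- data.frame(case_id = cf$patient_id[i],
                             control_id = pf$patient_id[j],
                             date_gap_days = gap[j],
                             stringsAsFactors = FALSE)
  }
  matched <- do.call(rbind, pairs[!vapply(pairs, is.null, TRUE)])
  if (is.null(matched))
    matched <- data.frame(case_id = character(), control_id = character(),
                          date_gap_days = numeric(), stringsAsFactors = FALSE)
  controls <- pool[pool$patient_id %in% matched$control_id, , drop = FALSE]
  rownames(controls) <- NULL
  list(
    pairs = matched,
    controls = new_discharge_records(controls),
    unmatched = setdiff(cf$patient_id, matched$case_id)
  )
}
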