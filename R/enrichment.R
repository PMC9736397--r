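#' Odds ratio with Woolf (log-normal) confidence interval
#'
#' For the 2x2 table (a = cases with disease, b = cases without, c =
#' controls with, d = controls without), OR = ad/bc with the Woolf CI
#' exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)). If any single cell is
#' zero the Haldane--Anscombe correction adds 0.5 to every cell and the
#' result is flagged `corrected`; if both cells of a margin are zero the
#' OR is undefined and returned as flagged `NaN`.
#'
#' @param a,b,c,d non-negative cell counts.
#' @param conf_level confidence level (default 0.95).
#' @return list with `or`, `ci_low`, `ci_high`, `corrected`, `undefined`.
#' @export
#' @examples
#' odds_ratio(803, 233, 213, 823)  # ~13.32 (10.80, 16.42)
odds_ratio <- function(a, b, c, d, conf_level = 0.95) {
  if (any(c(a, b, c, d) < 0)) stop_validation("cell counts must be >= 0")
  if ((a + b == 0) || (c + d == 0) || (a + c == 0) || (b + d == 0)) {
    return(list(or = NaN, ci_low = NaN, ci_high = NaN,
                corrected = FALSE, undefined = TRUE))
  }
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * c)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(
    or = or,
    ci_low = exp(log(or) - z * se),
    ci_high = exp(log(or) + z * se),
    corrected = corrected,
    undefined = FALSE
  )
}

#' Prevalence with exact or Wilson confidence interval
#'
#' Point estimate k/n with a Clopper--Pearson exact interval by default
#' (beta quantiles), or a Wilson score interval.
#'
#' @param k number of patients with the disease.
#' @param n group size (> 0).
#' @param method `"clopper-pearson"` or `"wilson"`.
#' @param conf_level confidence level.
#' @return list with `estimate`, `ci_low`, `ci_high`.
#' @export
prevalence_ci <- function(k, n, method = c("clopper-pearson", "wilson"),
                          conf_level = 0.95) {
  method <- match.arg(method)
  if (n <= 0) stop_validation("n must be > 0")
  if (k < 0 || k > n) stop_validation("k must be in [0, n]")
  alpha <- 1 - conf_level
  p <- k / n
  if (method == "clopper-pearson") {
    low <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
    high <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    low <- max(0, centre - half)
    high <- min(1, centre + half)
  }
  list(estimate = p, ci_low = low, ci_high = high)
}

.pair_test_p <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    stats::fisher.test(m)$p.value
  } else {
    suppressWarnings(stats::chisq.test(m, correct = TRUE)$p.value)
  }
}

#' Case-control enrichment table for every comorbidity
#'
#' For every disease in the case universe, builds the 2x2 table against
#' controls, computes prevalences with CIs, the Woolf odds ratio, and a
#' 2x2 test p-value (chi-square with continuity correction, Fisher exact
#' when any expected cell is below 5). Significance is Bonferroni-adjusted:
#' p < alpha / n_tests, with n_tests defaulting to the number of case
#' comorbidities. A disease is *enriched* when it is significant and its
#' OR exceeds `or_floor` (default 1.5).
#'
#' @param case_matrix,control_matrix `cohort_matrix` objects; diseases
#'   absent from controls contribute c = 0 (zero-cell rule applies).
#' @param alpha family-wise error target (default 0.05).
#' @param n_tests number of tests for the Bonferroni divisor; default
#'   `ncol(case_matrix$incidence)`.
#' @param or_floor enrichment OR threshold.
#' @param ci_method prevalence CI method, see [prevalence_ci()].
#' @return data frame, one row per disease, sorted by OR descending.
#' @export
enrich_table <- function(case_matrix, control_matrix, alpha = 0.05,
                         n_tests = NULL, or_floor = 1.5,
                         ci_method = "clopper-pearson") {
  stopifnot(inherits(case_matrix, "cohort_matrix"),
            inherits(control_matrix, "cohort_matrix"))
  diseases <- colnames(case_matrix$incidence)
  if (is.null(n_tests)) n_tests <- length(diseases)
  n_case <- case_matrix$n_patients
  n_ctrl <- control_matrix$n_patients

  rows <- lapply(diseases, function(code) {
    a <- sum(case_matrix$incidence[, code])
    c_ <- if (code %in% colnames(control_matrix$incidence))
      sum(control_matrix$incidence[, code]) else 0L
    b <- n_case - a
    d <- n_ctrl - c_
    or <- odds_ratio(a, b, c_, d)
    pc <- prevalence_ci(a, n_case, method = ci_method)
    pk <- prevalence_ci(c_, n_ctrl, method = ci_method)
    p <- .pair_test_p(a, b, c_, d)
    data.frame(
      code3 = code, a = a, b = b, c = c_, d = d,
      prevalence_case = pc$estimate, prev_case_low = pc$ci_low,
      prev_case_high = pc$ci_high,
      prevalence_control = pk$estimate, prev_control_low = pk$ci_low,
      prev_control_high = pk$ci_high,
      or = or$or, or_low = or$ci_low, or_high = or$ci_high,
      or_corrected = or$corrected,
      p_value = p,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$bonferroni_alpha <- alpha / n_tests
  out$significant <- !is.na(out$p_value) & out$p_value < alpha / n_tests
  out$enriched <- out$significant & !is.nan(out$or) & out$or > or_floor
  out[order(-out$or, out$code3, na.last = TRUE), , drop = FALSE]
}
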