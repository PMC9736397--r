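#' Frequent itemset mining by the Apriori algorithm
#'
#' Level-wise search over disease itemsets: level k candidates are joined
#' from frequent (k-1)-itemsets sharing their first k-2 items and pruned
#' by downward closure (every subset of a frequent itemset is frequent)
#' before supports are counted on the transaction matrix. Transactions are
#' the rows of the incidence matrix (patients by default).
#'
#' @param matrix a `cohort_matrix` or binary 0/1 matrix with column names.
#' @param min_support minimum support fraction in (0, 1]; itemsets with
#'   support >= `min_support` are returned.
#' @param max_len optional cap on itemset size.
#' @return data frame with list-column `items` (sorted character vectors),
#'   `size`, and `support`.
#' @export
apriori <- function(matrix, min_support = 0.01, max_len = Inf) {
  X <- if (inherits(matrix, "cohort_matrix")) matrix$incidence else matrix
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  if (min_support <= 0 || min_support > 1)
    stop_config("min_support must be in (0, 1]")
  n <- nrow(X)
  storage.mode(X) <- "numeric"

  support_of <- function(items) sum(rowSums(X[, items, drop = FALSE]) == length(items)) / n

  items1 <- sort(colnames(X))
  supp1 <- colMeans(X)[items1]
  frequent <- list()
  level <- lapply(items1[supp1 >= min_support], identity)
  level_supp <- supp1[supp1 >= min_support]
  k <- 1L
  while (length(level) > 0L && k <= max_len) {
    frequent[[k]] <- data.frame(
      items = I(level), size = k, support = as.numeric(level_supp),
      stringsAsFactors = FALSE
    )
    # candidate generation: join sets sharing the first k-1 items
    keys <- vapply(level, paste, "", collapse = "\r")
    cands <- list()
    if (length(level) > 1L) {
      prefix <- vapply(level, function(s) paste(s[-k], collapse = "\r"), "")
      for (p in unique(prefix)) {
        group <- level[prefix == p]
        if (length(group) < 2L) next
        lasts <- sort(vapply(group, function(s) s[k], ""))
        for (i in seq_len(length(lasts) - 1L)) {
          for (j in seq(i + 1L, length(lasts))) {
            cand <- c(if (nzchar(p)) strsplit(p, "\r", fixed = TRUE)[[1]],
                      lasts[i], lasts[j])
            # downward-closure prune: all k-subsets must be frequent
            subs_ok <- all(vapply(seq_along(cand), function(drop) {
              paste(cand[-drop], collapse = "\r") %in% keys
            }, TRUE))
            if (subs_ok) cands[[length(cands) + 1L]] <- cand
          }
        }
      }
    }
    if (length(cands) == 0L) break
    supp <- vapply(cands, support_of, numeric(1))
    keep <- supp >= min_support
    level <- cands[keep]
    level_supp <- supp[keep]
    k <- k + 1L
  }
  out <- do.call(rbind, frequent)
  if (is.null(out))
    out <- data.frame(items = I(list()), size = integer(), support = numeric())
  rownames(out) <- NULL
  out
}

#' The five association-rule metrics from marginal supports
#'
#' For a rule A -> C with P(A) = `antecedent_support`, P(A, C) = `support`
#' and P(C) = `consequent_support`:
#' confidence = P(A,C)/P(A); lift = confidence / P(C);
#' leverage = P(A,C) - P(A) P(C);
#' conviction = (1 - P(C)) / (1 - confidence), `Inf` when confidence = 1.
#'
#' @param antecedent_support,support,consequent_support numeric vectors.
#' @return data frame with columns `confidence`, `lift`, `leverage`,
#'   `conviction`.
#' @export
rule_metrics <- function(antecedent_support, support, consequent_support) {
  confidence <- support / antecedent_support
  data.frame(
    confidence = confidence,
    lift = confidence / consequent_support,
    leverage = support - antecedent_support * consequent_support,
    conviction = ifelse(confidence >= 1, Inf,
                        (1 - consequent_support) / (1 - confidence))
  )
}

#' Mine association rules targeted at a consequent disease
#'
#' Mines frequent itemsets with [apriori()], then forms rules
#' A -> consequent for every frequent itemset containing the consequent.
#' Thresholds are strict: rules are kept when support > `min_support` and
#' confidence > `min_confidence`. All five metrics of [rule_metrics()]
#' are attached, and rules are sorted by lift descending.
#'
#' @param matrix a `cohort_matrix` or binary matrix.
#' @param consequent disease code(s) forming the rule consequent
#'   (default `"I50"`, heart failure).
#' @param min_support,min_confidence strict thresholds (defaults 0.01 and
#'   0.5).
#' @param max_antecedent cap on antecedent size.
#' @return data frame with list-column `antecedent`, `consequent` (string,
#'   codes joined by ","), `antecedent_support`, `support`, `confidence`,
#'   `lift`, `leverage`, `conviction`.
#' @export
mine_rules <- function(matrix, consequent = "I50", min_support = 0.01,
                       min_confidence = 0.5, max_antecedent = 3L) {
  X <- if (inherits(matrix, "cohort_matrix")) matrix$incidence else matrix
  consequent <- sort(toupper(consequent))
  empty <- data.frame(
    antecedent = I(list()), consequent = character(),
    antecedent_support = numeric(), support = numeric(),
    confidence = numeric(), lift = numeric(), leverage = numeric(),
    conviction = numeric(), stringsAsFactors = FALSE
  )
  if (!all(consequent %in% colnames(X))) {
    warning("consequent absent from the data; no rules")
    return(empty)
  }
  sets <- apriori(X, min_support = min_support,
                  max_len = max_antecedent + length(consequent))
  if (nrow(sets) == 0L) return(empty)
  keys <- vapply(sets$items, paste, "", collapse = "\r")
  supp_of <- function(items) {
    i <- match(paste(sort(items), collapse = "\r"), keys)
    if (is.na(i)) NA_real_ else sets$support[i]
  }
  cons_supp <- sum(rowSums(X[, consequent, drop = FALSE]) ==
                     length(consequent)) / nrow(X)

  has_cons <- vapply(sets$items, function(s) all(consequent %in% s), TRUE) &
    sets$size > length(consequent)
  rows <- lapply(which(has_cons), function(i) {
    items <- sets$items[[i]]
    ante <- setdiff(items, consequent)
    ante_supp <- supp_of(ante)  # frequent by downward closure
    data.frame(
      antecedent = I(list(ante)),
      consequent = paste(consequent, collapse = ","),
      antecedent_support = ante_supp,
      support = sets$support[i],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- cbind(out, rule_metrics(out$antecedent_support, out$support, cons_supp))
  out <- out[out$support > min_support & out$confidence > min_confidence, ,
             drop = FALSE]
  out <- out[order(-out$lift), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "consequent_support") <- cons_supp
  out
}

#' Write mined rules as a CSV table
#'
#' Columns mirror the standard rule-table layout (antecedent codes,
#' consequent code, antecedent support, support, confidence, lift,
#' leverage, conviction), optionally rounded to 3 decimals.
#'
#' @param rules output of [mine_rules()].
#' @param path output CSV.
#' @param digits optional rounding (e.g. 3), NULL for full precision.
#' @export
write_rules <- function(rules, path, digits = NULL) {
  out <- data.frame(
    antecedent = vapply(rules$antecedent, paste, "", collapse = ";"),
    consequent = rules$consequent,
    antecedent_support = rules$antecedent_support,
    support = rules$support,
    confidence = rules$confidence,
    lift = rules$lift,
    leverage = rules$leverage,
    conviction = rules$conviction,
    stringsAsFactors = FALSE
  )
  if (!is.null(digits)) {
    num <- vapply(out, is.numeric, TRUE)
    out[num] <- lapply(out[num], round, digits = digits)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
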