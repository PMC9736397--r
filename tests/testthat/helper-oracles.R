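# Brute-force oracles and in-code fixtures shared across the suite.

rand_incidence <- function(n, m, p = 0.4, codes = NULL) {
  if (is.null(codes)) codes <- sprintf("D%02d", seq_len(m))
  matrix(rbinom(n * m, 1L, p), nrow = n, dimnames = list(NULL, codes))
}

as_cohort <- function(X, group = "case", stratum = "all") {
  pdnet:::new_cohort_matrix(X, group = group, stratum = stratum)
}

# --- Apriori oracle: exhaustive enumeration over all non-empty itemsets ---

enumerate_itemsets <- function(X, min_support) {
  items <- sort(colnames(X))
  out <- list()
  for (k in seq_along(items)) {
    combos <- utils::combn(items, k, simplify = FALSE)
    for (set in combos) {
      supp <- mean(rowSums(X[, set, drop = FALSE]) == k)
      if (supp >= min_support)
        out[[length(out) + 1L]] <- list(items = set, support = supp)
    }
  }
  out
}

itemset_key <- function(items) paste(sort(items), collapse = "|")

# --- Topology oracle: Floyd-Warshall plus shortest-path counting ---

graph_distance_matrix <- function(g, distance_rule) {
  n <- igraph::vcount(g)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- if (distance_rule == "unit") rep(1, nrow(el)) else
    1 / igraph::E(g)$weight
  for (e in seq_len(nrow(el))) {
    i <- el[e, 1]; j <- el[e, 2]
    D[i, j] <- D[j, i] <- min(D[i, j], w[e])
  }
  D
}

floyd_warshall <- function(D) {
  n <- nrow(D)
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# Number of shortest paths between every ordered pair, by DP over vertices
# sorted by distance from the source.
count_shortest_paths <- function(Dedge, Dall, tol = 1e-9) {
  n <- nrow(Dedge)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    ord <- order(Dall[s, ])
    for (v in ord) {
      if (v == s || !is.finite(Dall[s, v])) next
      for (u in seq_len(n)) {
        if (is.finite(Dedge[u, v]) && u != v &&
            abs(Dall[s, u] + Dedge[u, v] - Dall[s, v]) < tol)
          sigma[s, v] <- sigma[s, v] + sigma[s, u]
      }
    }
  }
  sigma
}

brute_topology <- function(g, distance_rule = "inverse_weight", tol = 1e-9) {
  n <- igraph::vcount(g)
  Dedge <- graph_distance_matrix(g, distance_rule)
  Dall <- floyd_warshall(Dedge)

  reach <- is.finite(Dall)
  comp_sizes <- rowSums(reach)
  lcc <- which(comp_sizes == max(comp_sizes))
  lcc <- which(reach[lcc[1], ])
  dl <- Dall[lcc, lcc, drop = FALSE]

  closeness <- vapply(seq_len(n), function(v) {
    others <- setdiff(which(reach[v, ]), v)
    if (length(others) == 0L) NA_real_ else 1 / sum(Dall[v, others])
  }, numeric(1))

  sigma <- count_shortest_paths(Dedge, Dall, tol)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq((s + 1), n)) {
      if (!is.finite(Dall[s, t]) || sigma[s, t] == 0) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (abs(Dall[s, v] + Dall[v, t] - Dall[s, t]) < tol)
          btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }

  list(
    density = igraph::ecount(g) / (n * (n - 1) / 2),
    diameter = if (length(lcc) < 2) 0 else max(dl),
    avg_path_length = if (length(lcc) < 2) 0 else mean(dl[upper.tri(dl)]),
    avg_closeness = mean(closeness, na.rm = TRUE),
    avg_betweenness = mean(btw)
  )
}

# --- Exact discrete power-law sampler (normalized zeta weights) ---

sample_discrete_powerlaw <- function(n, alpha, kmax = 1e5L) {
  k <- seq_len(kmax)
  p <- k^(-alpha)
  sample.int(kmax, n, replace = TRUE, prob = p / sum(p))
}

# --- Small record fixtures built in code ---

make_records <- function(patient_id, sex, age, date, department, diagnoses) {
  df <- data.frame(patient_id = patient_id, sex = sex, age_years = age,
                   discharge_date = as.Date(date), department = department,
                   stringsAsFactors = FALSE)
  df$diagnoses <- diagnoses
  pdnet:::new_discharge_records(df)
}

tiny_records <- function() {
  make_records(
    patient_id = c("p1", "p1", "p2", "p3"),
    sex = c("male", "male", "female", "male"),
    age = c(45L, 45L, 67L, 19L),
    date = c("2015-03-01", "2016-07-15", "2014-11-30", "2019-01-02"),
    department = c("cardiology", "cardiology", "internal_medicine", "cardiology"),
    diagnoses = list(c("I42.0", "I50"), c("I42.0", "E78.5"),
                     c("I10", "E11.9", "I50.0"), c("I42.9", "S72.1"))
  )
}
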