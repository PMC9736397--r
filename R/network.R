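#' Pairwise co-occurrence statistics for all disease pairs
#'
#' For diseases a, b with patient counts n_a, n_b, co-occurrence count
#' n_ab, and stratum size N:
#' \itemize{
#'   \item relative risk `RR = n_ab * N / (n_a * n_b)` — observed
#'     co-occurrence over the independence expectation;
#'   \item `phi` — the Pearson correlation of the two binary indicators;
#'   \item its t statistic `t = phi * sqrt((n - 2) / (1 - phi^2))` with
#'     `n = max(n_a, n_b)`;
#'   \item the Salton cosine index `SCI = n_ab / sqrt(n_a * n_b)`, the
#'     cosine similarity of the two patient sets and the network's edge
#'     weight. Unlike RR, SCI is invariant under replicating the sample.
#' }
#' `phi` (and its t) are undefined when a marginal is 0 or N; `|phi| = 1`
#' gives an infinite t. Both situations are flagged via NaN/Inf.
#'
#' @param matrix a `cohort_matrix`.
#' @return data frame with one row per unordered pair: `a`, `b`, `n_a`,
#'   `n_b`, `n_ab`, `n_total`, `rr`, `phi`, `t_stat`, `p_edge`
#'   (two-sided, df = n - 2), `sci`.
#' @export
pair_stats_all <- function(matrix) {
  stopifnot(inherits(matrix, "cohort_matrix"))
  X <- matrix$incidence
  if (ncol(X) < 2L) stop_validation("need at least 2 diseases")
  N <- nrow(X)
  co <- crossprod(X)                      # n_ab on off-diagonal, n_a on diag
  n <- diag(co)
  idx <- which(upper.tri(co), arr.ind = TRUE)
  a <- colnames(X)[idx[, 1]]
  b <- colnames(X)[idx[, 2]]
  n_a <- n[idx[, 1]]
  n_b <- n[idx[, 2]]
  n_ab <- co[idx]

  rr <- ifelse(n_a > 0 & n_b > 0, n_ab * N / (n_a * n_b), NaN)
  denom <- n_a * n_b * (N - n_a) * (N - n_b)
  phi <- ifelse(denom > 0, (n_ab * N - n_a * n_b) / sqrt(denom), NaN)
  nmax <- pmax(n_a, n_b)
  t_stat <- ifelse(abs(phi) < 1,
                   phi * sqrt(pmax(nmax - 2, 0) / (1 - phi^2)),
                   sign(phi) * Inf)
  p_edge <- rep(NaN, length(phi))
  ok <- !is.nan(phi)
  p_edge[ok] <- 2 * stats::pt(-abs(t_stat[ok]), df = pmax(nmax[ok] - 2, 1))
  sci <- ifelse(n_a > 0 & n_b > 0, n_ab / sqrt(n_a * n_b), 0)

  data.frame(a = a, b = b, n_a = n_a, n_b = n_b, n_ab = n_ab, n_total = N,
             rr = rr, phi = phi, t_stat = t_stat, p_edge = p_edge, sci = sci,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Co-occurrence statistics for one disease pair
#'
#' @param matrix a `cohort_matrix`.
#' @param a,b distinct disease codes present in the matrix.
#' @return one-row data frame, see [pair_stats_all()].
#' @export
pair_stats <- function(matrix, a, b) {
  if (identical(a, b)) stop_validation("a and b must differ")
  cols <- colnames(matrix$incidence)
  if (!all(c(a, b) %in% cols))
    stop_validation("both diseases must be columns of the matrix")
  ps <- pair_stats_all(matrix)
  ps[(ps$a == a & ps$b == b) | (ps$a == b & ps$b == a), , drop = FALSE]
}

#' Build the weighted multimorbidity network for one stratum
#'
#' Nodes are the matrix's diseases (with prevalence and ICD-10 chapter as
#' attributes); edges carry the SCI as weight. An edge (a, b) is retained
#' iff all enabled criteria hold: co-occurrence count `n_ab >=
#' min_cooccurrence` (default 2), `SCI >= sci_cutoff` (disabled by
#' default), and the pair's phi t-test two-sided p below `alpha_edge`
#' (default 0.05). Each criterion is disabled by passing `NULL`. The
#' realized minimum SCI among retained edges is reported for comparison
#' across networks.
#'
#' @param matrix a `cohort_matrix` with >= 2 diseases.
#' @param min_cooccurrence minimum co-occurrence count, or NULL.
#' @param sci_cutoff absolute SCI threshold, or NULL.
#' @param alpha_edge significance level for the phi t-test, or NULL.
#' @return an `mm_network`: list with `graph` (igraph), `group`,
#'   `stratum`, `n_patients`, `min_sci`, and the full `pair_stats` table.
#' @export
build_network <- function(matrix, min_cooccurrence = 2L, sci_cutoff = NULL,
                          alpha_edge = 0.05) {
  ps <- pair_stats_all(matrix)
  keep <- ps$n_ab > 0 & ps$sci > 0
  if (!is.null(min_cooccurrence)) keep <- keep & ps$n_ab >= min_cooccurrence
  if (!is.null(sci_cutoff)) keep <- keep & ps$sci >= sci_cutoff
  if (!is.null(alpha_edge))
    keep <- keep & !is.nan(ps$p_edge) & ps$p_edge < alpha_edge
  edges <- ps[keep, c("a", "b", "sci", "n_ab", "rr", "phi"), drop = FALSE]

  vertices <- data.frame(
    name = colnames(matrix$incidence),
    prevalence = as.numeric(matrix$prevalence),
    chapter = icd10_chapter(colnames(matrix$incidence)),
    stringsAsFactors = FALSE
  )
  names(edges)[3] <- "weight"
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  if (nrow(edges) == 0L)
    warning(sprintf("no edges survive the cutoffs (%s/%s)",
                    matrix$group, matrix$stratum))
  structure(
    list(
      graph = g,
      group = matrix$group,
      stratum = matrix$stratum,
      n_patients = matrix$n_patients,
      min_sci = if (nrow(edges)) min(edges$weight) else NA_real_,
      pair_stats = ps
    ),
    class = "mm_network"
  )
}

#' @export
print.mm_network <- function(x, ...) {
  cat(sprintf("mm_network: %s / %s, %d nodes, %d edges, min SCI %s\n",
              x$group, x$stratum, igraph::vcount(x$graph),
              igraph::ecount(x$graph),
              ifelse(is.na(x$min_sci), "NA", sprintf("%.3f", x$min_sci))))
  invisible(x)
}

.edge_distances <- function(g, distance_rule) {
  if (igraph::ecount(g) == 0L) return(numeric())
  if (distance_rule == "unit") rep(1, igraph::ecount(g))
  else 1 / igraph::E(g)$weight
}

#' Structural summary of a multimorbidity network
#'
#' Density; diameter and average path length on the largest connected
#' component; and mean closeness, betweenness, degree, and average
#' neighbour degree over nodes. Shortest-path distances use either
#' `1/SCI` (stronger comorbidity = closer; default) or unit edge lengths.
#'
#' @param net an `mm_network`.
#' @param distance_rule `"inverse_weight"` or `"unit"`.
#' @return list of scalar summaries; `singleton` flags a network whose
#'   largest component has a single node (diameter reported as 0).
#' @export
topology <- function(net, distance_rule = c("inverse_weight", "unit")) {
  distance_rule <- match.arg(distance_rule)
  g <- net$graph
  if (igraph::vcount(g) == 0L) stop_validation("empty network")
  dw <- .edge_distances(g, distance_rule)

  comp <- igraph::components(g)
  lcc_ids <- which(comp$membership == which.max(comp$csize))
  lcc <- igraph::induced_subgraph(g, lcc_ids)
  singleton <- igraph::vcount(lcc) < 2L

  if (singleton) {
    diameter <- 0
    apl <- 0
  } else {
    dmat <- igraph::distances(lcc, weights = .edge_distances(lcc, distance_rule))
    diameter <- max(dmat)
    apl <- mean(dmat[upper.tri(dmat)])
  }
  deg <- igraph::degree(g)
  clo <- suppressWarnings(igraph::closeness(g, weights = dw))
  btw <- igraph::betweenness(g, weights = dw)
  knn <- suppressWarnings(igraph::knn(g, weights = NA)$knn)

  list(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    density = igraph::edge_density(g),
    diameter = diameter,
    avg_path_length = apl,
    avg_closeness = mean(clo, na.rm = TRUE),
    avg_betweenness = mean(btw),
    avg_degree = mean(deg),
    avg_neighbour_degree = mean(knn, na.rm = TRUE),
    min_sci = net$min_sci,
    singleton = singleton
  )
}

# Principal nonnegative eigenvector of a PSD nonnegative matrix by power
# iteration from the ones vector. Starting at 1 makes the limit
# deterministic even when the top eigenvalue is degenerate (e.g. the
# adjacency of a star component).
.power_iterate <- function(M, tol = 1e-13, max_iter = 1000L) {
  v <- rep(1, nrow(M)) / sqrt(nrow(M))
  for (it in seq_len(max_iter)) {
    v_new <- as.numeric(M %*% v)
    nrm <- sqrt(sum(v_new^2))
    if (nrm == 0) return(list(vector = v_new, iterations = it))
    v_new <- v_new / nrm
    if (max(abs(v_new - v)) < tol)
      return(list(vector = v_new, iterations = it))
    v <- v_new
  }
  stop_validation(sprintf(
    "HITS power iteration did not converge in %d iterations (last delta %.3g, n = %d)",
    max_iter, max(abs(v_new - v)), nrow(M)))
}

# HITS scores: hub = principal eigenvector of W W^T, authority = of W^T W,
# each scaled to max 1. On an undirected network the two matrices are both
# W^2, so hub and authority coincide. Non-convergence within the iteration
# cap raises a classed error with diagnostics.
.hits_symmetric <- function(g, tol = 1e-13, max_iter = 1000L) {
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  if (igraph::ecount(g) == 0L) {
    z <- stats::setNames(rep(0, n), nm)
    return(list(hub = z, authority = z, iterations = 0L))
  }
  W <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  scale1 <- function(v) if (max(v) > 0) v / max(v) else v
  auth <- .power_iterate(crossprod(W), tol = tol, max_iter = max_iter)
  hub <- .power_iterate(tcrossprod(W), tol = tol, max_iter = max_iter)
  list(hub = stats::setNames(scale1(hub$vector), nm),
       authority = stats::setNames(scale1(auth$vector), nm),
       iterations = max(auth$iterations, hub$iterations))
}

# Clauset-style sampler for a discrete power law above xmin: continuous
# approximation rounded to integers.
.rpowerlaw_discrete <- function(n, alpha, xmin) {
  u <- stats::runif(n)
  floor((xmin - 0.5) * (1 - u)^(-1 / (alpha - 1)) + 0.5)
}

#' Power-law fit and goodness of fit for the degree distribution
#'
#' Fits a discrete power law above `x_min` by maximum likelihood with
#' `x_min` chosen by KS minimization, then assesses plausibility with a
#' semi-parametric bootstrap: synthetic degree samples are drawn from the
#' fitted tail (empirical body below `x_min`), refitted, and the p-value
#' is the share of bootstrap KS distances at least as large as the
#' observed one. Small p-values reject the power law.
#'
#' @param x an `mm_network` or a vector of node degrees (>= 10 values).
#' @param reps bootstrap replicates (default 200).
#' @param xmin optionally fix `x_min` instead of KS minimization.
#' @return list with `alpha`, `xmin`, `ks_stat`, `p_value`, `n_tail`,
#'   `reps`, `degenerate`. All-equal degrees are flagged `degenerate`
#'   with no fit.
#' @export
degree_powerlaw_test <- function(x, reps = 200L, xmin = NULL) {
  degrees <- if (inherits(x, "mm_network")) igraph::degree(x$graph) else x
  degrees <- degrees[degrees > 0]
  if (length(degrees) < 10L)
    stop_validation("need at least 10 positive degrees")
  if (length(unique(degrees)) == 1L) {
    return(list(alpha = NA_real_, xmin = NA_real_, ks_stat = NA_real_,
                p_value = NA_real_, n_tail = length(degrees), reps = 0L,
                degenerate = TRUE))
  }
  fit <- igraph::fit_power_law(degrees, xmin = xmin,
                               implementation = "plfit")
  obs_ks <- fit$KS.stat
  body <- degrees[degrees < fit$xmin]
  p_tail <- mean(degrees >= fit$xmin)
  n <- length(degrees)

  ks_boot <- vapply(seq_len(reps), function(r) {
    tail_draw <- stats::rbinom(1, n, p_tail)
    synth <- c(
      .rpowerlaw_discrete(tail_draw, fit$alpha, fit$xmin),
      if (n - tail_draw > 0 && length(body) > 0)
        sample(body, n - tail_draw, replace = TRUE)
      else
        .rpowerlaw_discrete(n - tail_draw, fit$alpha, fit$xmin)
    )
    bf <- try(igraph::fit_power_law(synth, implementation = "plfit"),
              silent = TRUE)
    if (inherits(bf, "try-error")) NA_real_ else bf$KS.stat
  }, numeric(1))
  ks_boot <- ks_boot[!is.na(ks_boot)]

  list(
    alpha = fit$alpha,
    xmin = fit$xmin,
    ks_stat = obs_ks,
    p_value = if (length(ks_boot)) mean(ks_boot >= obs_ks) else NA_real_,
    n_tail = sum(degrees >= fit$xmin),
    reps = length(ks_boot),
    degenerate = FALSE
  )
}

#' Nodes in the top percentile of a score
#'
#' Role sets contain the nodes whose score is strictly above the
#' `1 - percentile` quantile (default: above the 90th percentile). Nodes
#' tied on a score are treated alike — either all admitted or all
#' excluded — so the set size is about `percentile * n`, deviating only
#' at ties. If every score is equal the set is empty.
#'
#' @param scores named numeric vector.
#' @param percentile target fraction of nodes (default 0.10).
#' @return character vector of names.
#' @export
top_percentile_set <- function(scores, percentile = 0.10) {
  stopifnot(!is.null(names(scores)))
  threshold <- stats::quantile(scores, 1 - percentile, names = FALSE)
  names(scores)[scores > threshold]
}

#' Node roles: central (PageRank), hub and authority (HITS)
#'
#' Weighted PageRank (damping 0.85) and HITS hub/authority scores are
#' computed with SCI edge weights; the central/hub/authority role sets are
#' the top 10th percentile of each score (ties included). On an undirected
#' graph HITS runs on the symmetric weighted adjacency, so hub and
#' authority scores coincide mathematically; both columns are still
#' reported because consumers expect both.
#'
#' @param net an `mm_network`.
#' @param percentile role-set percentile (default 0.10).
#' @return data frame with one row per node: scores plus logical
#'   `is_central`, `is_hub`, `is_authority`; attribute `role_sets` holds
#'   the three name vectors.
#' @export
node_roles <- function(net, percentile = 0.10) {
  g <- net$graph
  if (igraph::vcount(g) == 0L) stop_validation("empty network")
  w <- if (igraph::ecount(g) > 0L) igraph::E(g)$weight else NULL
  pr <- igraph::page_rank(g, damping = 0.85, weights = w)$vector
  hits <- .hits_symmetric(g)
  hub <- hits$hub
  auth <- hits$authority

  central_set <- top_percentile_set(pr, percentile)
  hub_set <- top_percentile_set(hub, percentile)
  auth_set <- top_percentile_set(auth, percentile)

  out <- data.frame(
    code3 = names(pr),
    pagerank = as.numeric(pr),
    hub = as.numeric(hub),
    authority = as.numeric(auth),
    is_central = names(pr) %in% central_set,
    is_hub = names(pr) %in% hub_set,
    is_authority = names(pr) %in% auth_set,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order(-out$pagerank), , drop = FALSE]
  attr(out, "role_sets") <- list(central = central_set, hub = hub_set,
                                 authority = auth_set)
  attr(out, "stratum") <- net$stratum
  attr(out, "group") <- net$group
  out
}

#' Count role appearances of each disease across strata
#'
#' @param roles_list list of [node_roles()] tables (one per stratum).
#' @return data frame: code3, central/hub/authority appearance counts and
#'   the number of strata in which the disease occurs at all.
#' @export
role_appearance <- function(roles_list) {
  roles_list <- roles_list[!vapply(roles_list, is.null, TRUE)]
  all_codes <- sort(unique(unlist(lapply(roles_list, `[[`, "code3"))))
  count_role <- function(col) {
    vapply(all_codes, function(code) {
      sum(vapply(roles_list, function(r) {
        i <- match(code, r$code3)
        !is.na(i) && r[[col]][i]
      }, TRUE))
    }, integer(1))
  }
  data.frame(
    code3 = all_codes,
    n_strata = vapply(all_codes, function(code) {
      sum(vapply(roles_list, function(r) code %in% r$code3, TRUE))
    }, integer(1)),
    central = count_role("is_central"),
    hub = count_role("is_hub"),
    authority = count_role("is_authority"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Cumulative SCI of role versus non-role nodes
#'
#' For each network and role type, sums the SCI of edges incident to role
#' nodes (node strength) and to the remaining nodes, quantifying how much
#' more connected the "typical" diseases are.
#'
#' @param nets named list of `mm_network` objects (e.g. per stratum).
#' @param roles_list matching list of [node_roles()] tables.
#' @return data frame: stratum, role, cumulative SCI for role nodes and
#'   non-role nodes, node counts.
#' @export
cumulative_role_sci <- function(nets, roles_list) {
  stopifnot(length(nets) == length(roles_list))
  rows <- list()
  for (i in seq_along(nets)) {
    net <- nets[[i]]
    roles <- roles_list[[i]]
    if (is.null(net) || is.null(roles)) next
    strength <- igraph::strength(net$graph)
    sets <- attr(roles, "role_sets")
    for (role in names(sets)) {
      in_role <- names(strength) %in% sets[[role]]
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = net$stratum,
        role = role,
        role_sci_sum = sum(strength[in_role]),
        nonrole_sci_sum = sum(strength[!in_role]),
        n_role = sum(in_role),
        n_nonrole = sum(!in_role),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Export a network as GraphML, edge list, and node table
#'
#' @param net an `mm_network`.
#' @param graphml,edges_tsv,nodes_csv output paths (NULL to skip).
#' @param roles optional [node_roles()] table to merge into the node CSV.
#' @export
write_network <- function(net, graphml = NULL, edges_tsv = NULL,
                          nodes_csv = NULL, roles = NULL) {
  g <- net$graph
  if (!is.null(graphml))
    igraph::write_graph(g, graphml, format = "graphml")
  if (!is.null(edges_tsv)) {
    el <- igraph::as_data_frame(g, what = "edges")
    names(el)[names(el) == "from"] <- "code_a"
    names(el)[names(el) == "to"] <- "code_b"
    names(el)[names(el) == "weight"] <- "sci"
    utils::write.table(el, edges_tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  if (!is.null(nodes_csv)) {
    nodes <- igraph::as_data_frame(g, what = "vertices")
    names(nodes)[names(nodes) == "name"] <- "code3"
    nodes$degree <- igraph::degree(g)
    nodes$strength <- igraph::strength(g)
    dw <- .edge_distances(g, "inverse_weight")
    nodes$closeness <- suppressWarnings(igraph::closeness(g, weights = dw))
    nodes$betweenness <- igraph::betweenness(g, weights = dw)
    if (!is.null(roles))
      nodes <- merge(nodes, roles, by = "code3", all.x = TRUE, sort = FALSE)
    utils::write.csv(nodes, nodes_csv, row.names = FALSE)
  }
  invisible(net)
}
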