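test_that("pair statistics match hand arithmetic on degenerate columns", {
  X <- matrix(0L, 100, 2, dimnames = list(NULL, c("A01", "B18")))
  X[1:10, ] <- 1L
  ps <- pair_stats(as_cohort(X), "A01", "B18")
  expect_equal(ps$sci, 1)
  expect_equal(ps$rr, 10)

  X2 <- matrix(0L, 50, 2, dimnames = list(NULL, c("A01", "B18")))
  X2[1:10, 1] <- 1L; X2[11:20, 2] <- 1L
  ps2 <- pair_stats(as_cohort(X2), "A01", "B18")
  expect_equal(ps2$sci, 0)
  expect_equal(ps2$rr, 0)
})

test_that("the SCI/RR identity SCI^2 * N = RR * n_ab holds to 1e-12", {
  set.seed(5)
  for (i in 1:200) {
    X <- rand_incidence(sample(10:80, 1), 2, p = runif(1, 0.1, 0.9))
    ps <- pair_stats_all(as_cohort(X))
    if (ps$n_a == 0 || ps$n_b == 0) next
    expect_equal(ps$sci^2 * ps$n_total, ps$rr * ps$n_ab, tolerance = 1e-12)
  }
})

test_that("SCI and RR are invariant under duplicating every patient", {
  set.seed(9)
  X <- rand_incidence(40, 4, p = 0.4)
  ps1 <- pair_stats_all(as_cohort(X))
  ps2 <- pair_stats_all(as_cohort(rbind(X, X)))
  expect_equal(ps2$sci, ps1$sci, tolerance = 1e-12)
  expect_equal(ps2$rr, ps1$rr, tolerance = 1e-12)
  expect_equal(ps2$n_ab, 2 * ps1$n_ab)
})

test_that("perfect co-occurrence builds a complete triangle at weight 1", {
  X <- matrix(1L, 20, 3, dimnames = list(NULL, c("I50", "I34", "I36")))
  net <- build_network(as_cohort(X), alpha_edge = NULL)
  expect_equal(igraph::ecount(net$graph), 3)
  expect_true(all(igraph::E(net$graph)$weight == 1))
  expect_equal(topology(net)$density, 1)
  expect_equal(net$min_sci, 1)
})

test_that("the edge set shrinks monotonically in the SCI cutoff", {
  set.seed(13)
  X <- rand_incidence(80, 8, p = 0.35)
  cuts <- c(0, 0.2, 0.4, 0.6, 0.8)
  sizes <- vapply(cuts, function(ct) {
    suppressWarnings(
      igraph::ecount(build_network(as_cohort(X), sci_cutoff = ct,
                                   alpha_edge = NULL,
                                   min_cooccurrence = 1L)$graph))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("path and complete graphs have textbook topology", {
  X <- matrix(0L, 30, 3, dimnames = list(NULL, c("A01", "B18", "C18")))
  X[1:10, 1] <- 1L; X[6:20, 2] <- 1L; X[16:25, 3] <- 1L
  net <- build_network(as_cohort(X), alpha_edge = NULL, min_cooccurrence = 1L)
  expect_equal(igraph::ecount(net$graph), 2)  # A-B and B-C share patients
  t_unit <- topology(net, distance_rule = "unit")
  expect_equal(t_unit$diameter, 2)
  expect_equal(t_unit$avg_path_length, 4 / 3)
})

test_that("small-network topology agrees with the brute-force oracle", {
  set.seed(17)
  checked <- 0L
  for (i in 1:40) {
    X <- rand_incidence(12, sample(3:8, 1), p = runif(1, 0.3, 0.7))
    net <- suppressWarnings(
      build_network(as_cohort(X), alpha_edge = NULL, min_cooccurrence = 1L))
    if (igraph::ecount(net$graph) == 0) next
    for (rule in c("inverse_weight", "unit")) {
      got <- topology(net, distance_rule = rule)
      want <- brute_topology(net$graph, distance_rule = rule)
      for (stat in names(want))
        expect_equal(got[[stat]], want[[stat]], tolerance = 1e-9,
                     label = sprintf("%s (%s, rep %d)", stat, rule, i))
    }
    checked <- checked + 1L
  }
  expect_gte(checked, 20L)
})

test_that("the power-law fit recovers a known exponent and flags degeneracy", {
  set.seed(1)
  degrees <- sample_discrete_powerlaw(500, alpha = 2.5)
  fit <- degree_powerlaw_test(degrees, reps = 50)
  expect_lt(abs(fit$alpha - 2.5), 0.3)
  expect_gte(fit$p_value, 0)

  flat <- degree_powerlaw_test(rep(4, 30), reps = 10)
  expect_true(flat$degenerate)
  expect_true(is.na(flat$alpha))
})

test_that("a Poisson degree sample is implausible under a power law", {
  set.seed(2)
  degrees <- rpois(800, lambda = 8) + 1L
  fit <- degree_powerlaw_test(degrees, reps = 100)
  expect_lt(fit$p_value, 0.10)
})

test_that("the star centre dominates PageRank and HITS", {
  X <- matrix(0L, 60, 6,
              dimnames = list(NULL, c("I50", "E11", "E78", "G47", "I10", "N18")))
  set.seed(19)
  X[, 1] <- 1L
  for (j in 2:6) X[sample(60, 15), j] <- 1L
  net <- build_network(as_cohort(X), alpha_edge = NULL, min_cooccurrence = 1L)
  roles <- node_roles(net)
  expect_equal(roles$code3[which.max(roles$pagerank)], "I50")
  expect_true("I50" %in% attr(roles, "role_sets")$central)
})

test_that("hub and authority coincide on undirected weighted networks", {
  set.seed(29)
  for (i in 1:10) {
    X <- rand_incidence(50, sample(4:10, 1), p = runif(1, 0.3, 0.6))
    net <- suppressWarnings(
      build_network(as_cohort(X), alpha_edge = NULL, min_cooccurrence = 1L))
    roles <- node_roles(net)
    expect_lt(max(abs(roles$hub - roles$authority)), 1e-8)
  }
})

test_that("PageRank sums to one over the nodes", {
  set.seed(37)
  X <- rand_incidence(60, 8, p = 0.4)
  roles <- node_roles(build_network(as_cohort(X), alpha_edge = NULL,
                                    min_cooccurrence = 1L))
  expect_equal(sum(roles$pagerank), 1, tolerance = 1e-10)
})

test_that("cumulative SCI of role nodes dominates on a star", {
  X <- matrix(0L, 60, 6,
              dimnames = list(NULL, c("I50", "E11", "E78", "G47", "I10", "N18")))
  set.seed(41)
  X[, 1] <- 1L
  for (j in 2:6) X[sample(60, 15), j] <- 1L
  net <- build_network(as_cohort(X), alpha_edge = NULL, min_cooccurrence = 1L)
  roles <- node_roles(net)
  cum <- cumulative_role_sci(list(all = net), list(all = roles))
  central <- cum[cum$role == "central", ]
  expect_gte(central$role_sci_sum, 0)
  # the centre alone carries at least as much strength as any single other node
  strength <- igraph::strength(net$graph)
  expect_equal(names(which.max(strength)), "I50")
})

test_that("role appearance counts aggregate across strata", {
  set.seed(43)
  nets <- lapply(1:3, function(i) {
    X <- rand_incidence(50, 6, p = 0.5,
                        codes = c("I50", "E11", "E78", "G47", "I10", "N18"))
    suppressWarnings(build_network(as_cohort(X, stratum = as.character(i)),
                                   alpha_edge = NULL, min_cooccurrence = 1L))
  })
  roles <- lapply(nets, node_roles)
  app <- role_appearance(roles)
  expect_equal(nrow(app), 6L)
  expect_true(all(app$central <= app$n_strata))
  expect_true(all(app$n_strata == 3L))
})

test_that("network export writes GraphML, edge list, and node table", {
  set.seed(47)
  X <- rand_incidence(50, 5, p = 0.5)
  net <- suppressWarnings(build_network(as_cohort(X), alpha_edge = NULL,
                                        min_cooccurrence = 1L))
  g <- withr::local_tempfile(fileext = ".graphml")
  e <- withr::local_tempfile(fileext = ".tsv")
  v <- withr::local_tempfile(fileext = ".csv")
  write_network(net, graphml = g, edges_tsv = e, nodes_csv = v,
                roles = node_roles(net))
  back <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::ecount(back), igraph::ecount(net$graph))
  edges <- read.delim(e)
  expect_named(edges, c("code_a", "code_b", "sci", "n_ab", "rr", "phi"))
  nodes <- read.csv(v)
  expect_true(all(c("code3", "pagerank", "betweenness") %in% names(nodes)))
})
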