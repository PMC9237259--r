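test_that("interregional correlation equals the pairwise Pearson formula", {
  # exact linear dependence
  a <- c(1, 2, 4, 6, 7, 9)
  co <- tiny_cohort(cbind(A = a, B = 2 * a, C = c(5, 3, 8, 1, 9, 2)),
                    group = "Naive")
  net <- interregional_correlation(co, "Naive")
  expect_equal(net$weight["A", "B"], 1.0, tolerance = 1e-12)
  expect_equal(net$n_animals, 6)
  pear <- function(x, y) {
    n <- length(x)
    (n * sum(x * y) - sum(x) * sum(y)) /
      sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  }
  for (p in list(c("A", "B"), c("A", "C"), c("B", "C")))
    expect_equal(net$weight[p[1], p[2]], pear(co[[p[1]]], co[[p[2]]]),
                 tolerance = 1e-12)
  expect_true(isSymmetric(net$weight))
  expect_equal(diag(net$weight), setNames(rep(1, 3), c("A", "B", "C")))
  # zero-variance region reported missing with a warning naming it
  co$C <- 4
  expect_warning(net2 <- interregional_correlation(co, "Naive"),
                 "zero-variance.*C")
  expect_true(all(is.na(net2$weight["C", c("A", "B")])))
  expect_error(interregional_correlation(co[1:2, ], "Naive"), "need >= 3")
})

test_that("planted motor structure is recovered pairwise at n = 1000", {
  scen <- make_recovery_scenario("naive_motor_9edges")
  co <- suppressWarnings(
    generate_cohort(scen$summary, 1000, scen$corr_specs, seed = 31,
                    groups = "Naive"))
  net <- interregional_correlation(co, "Naive")
  ut <- upper.tri(scen$truth)
  # supra pairs (r >= 0.6) have small sampling error at n = 1000; the
  # near-zero pairs get the generic Monte-Carlo bound
  supra <- ut & scen$truth > 0.5
  expect_lt(max(abs(net$weight[supra] - scen$truth[supra])), 0.05)
  expect_lt(max(abs(net$weight[ut] - scen$truth[ut])), 0.1)
})

test_that("thresholding is strict, mode-aware, and keeps isolated nodes", {
  W <- diag(3)
  dimnames(W) <- list(c("A", "B", "C"), c("A", "B", "C"))
  W["A", "B"] <- W["B", "A"] <- 0.7
  W["A", "C"] <- W["C", "A"] <- 0.55
  W["B", "C"] <- W["C", "B"] <- -0.9
  net <- fosnet:::corr_network("g", c("A", "B", "C"), W, "pearson", 6)
  signed <- threshold_network(net, 0.6)
  expect_equal(edge_count(signed), 1)
  absolute <- threshold_network(net, 0.6, mode = "absolute")
  expect_equal(edge_count(absolute), 2)
  # boundary equality is excluded (strict >)
  expect_equal(edge_count(threshold_network(net, 0.55)), 1)
  expect_equal(edge_count(threshold_network(net, 0.549)), 2)
  # all-zero matrix: zero edges, every node present
  Z <- diag(3); dimnames(Z) <- dimnames(W)
  gz <- threshold_network(fosnet:::corr_network("g", c("A", "B", "C"), Z,
                                                "pearson", 6), 0.3)
  expect_equal(edge_count(gz), 0)
  expect_setequal(igraph::V(gz$graph)$name, c("A", "B", "C"))
  # missing weights are skipped and counted
  W["A", "C"] <- W["C", "A"] <- NA
  gm <- threshold_network(fosnet:::corr_network("g", c("A", "B", "C"), W,
                                                "pearson", 6), 0.6)
  expect_equal(gm$n_missing, 1)
  expect_equal(edge_count(gm), 1)
  expect_error(threshold_network(net, 1.2), "tau")
})

test_that("degree matches the adjacency-row-sum oracle", {
  # complete graph on 4 nodes
  nodes <- LETTERS[1:4]
  cmb <- t(combn(nodes, 2))
  g4 <- graph_fixture(nodes, data.frame(from = cmb[, 1], to = cmb[, 2],
                                        weight = 0.8))
  expect_equal(unname(degree_centrality(g4)), rep(3, 4))
  # isolated node
  giso <- graph_fixture(c("A", "B", "C"),
                        data.frame(from = "A", to = "B", weight = 0.9))
  expect_equal(degree_centrality(giso)[["C"]], 0)
  # random 12-node graph vs adjacency row sums
  set.seed(5)
  nodes <- paste0("n", 1:12)
  cmb <- t(combn(nodes, 2))
  keep <- runif(nrow(cmb)) < 0.25
  g12 <- graph_fixture(nodes, data.frame(from = cmb[keep, 1],
                                         to = cmb[keep, 2],
                                         weight = runif(sum(keep), 0.5, 1)))
  adj <- igraph::as_adjacency_matrix(g12$graph, sparse = FALSE)
  expect_equal(degree_centrality(g12), rowSums(adj))
  # strength variant sums absolute weights
  expect_equal(degree_centrality(giso, weighted = TRUE)[["A"]], 0.9)
})

test_that("betweenness matches hand values and brute-force enumeration", {
  # path A-B-C: B lies on the single A..C shortest path
  path <- graph_fixture(c("A", "B", "C"),
                        data.frame(from = c("A", "B"), to = c("B", "C"),
                                   weight = 1))
  expect_equal(betweenness_centrality(path)[["B"]], 1)
  expect_equal(betweenness_centrality(path)[["A"]], 0)
  # star with 4 leaves: center on all C(4,2) = 6 leaf pairs
  star <- graph_fixture(c("hub", paste0("l", 1:4)),
                        data.frame(from = "hub", to = paste0("l", 1:4),
                                   weight = 1))
  b <- betweenness_centrality(star)
  expect_equal(b[["hub"]], 6)
  expect_equal(unname(b[paste0("l", 1:4)]), rep(0, 4))
  # random 10-node graphs vs exhaustive path enumeration
  set.seed(6)
  for (rep in 1:3) {
    nodes <- paste0("n", 1:10)
    cmb <- t(combn(nodes, 2))
    keep <- runif(nrow(cmb)) < 0.25
    g <- graph_fixture(nodes, data.frame(from = cmb[keep, 1],
                                         to = cmb[keep, 2], weight = 1))
    expect_equal(betweenness_centrality(g), brute_betweenness(g$graph),
                 tolerance = 1e-10)
  }
})

test_that("hub identification combines degree and betweenness criteria", {
  # empty graph: no hubs
  empty <- graph_fixture(LETTERS[1:5])
  expect_equal(sum(identify_hubs(empty)$hub), 0)
  # unique hub: high-degree, high-betweenness center
  star6 <- graph_fixture(c("hub", paste0("l", 1:6)),
                         data.frame(from = "hub", to = paste0("l", 1:6),
                                    weight = 1))
  rep <- identify_hubs(star6, degree_min = 5, betweenness_top_k = 1)
  expect_equal(rep$region[rep$hub], "hub")
  expect_equal(rep$degree[rep$region == "hub"], 6)
  # constructed two-hub graph, checked by independent enumeration:
  # X and Y bridge two cliques and also have degree >= 5
  cliq <- function(nodes) {
    cmb <- t(combn(nodes, 2))
    data.frame(from = cmb[, 1], to = cmb[, 2], weight = 1)
  }
  edges <- rbind(cliq(c("X", paste0("a", 1:4))), cliq(c("Y", paste0("b", 1:4))),
                 data.frame(from = "X", to = "Y", weight = 1))
  g2 <- graph_fixture(c("X", "Y", paste0("a", 1:4), paste0("b", 1:4)), edges)
  hr <- identify_hubs(g2, degree_min = 5, betweenness_top_k = 2)
  expect_setequal(hr$region[hr$hub], c("X", "Y"))
  deg_ok <- names(which(degree_centrality(g2) >= 5))
  btw <- brute_betweenness(g2$graph)
  btw_rank <- rank(-btw, ties.method = "min")
  expect_setequal(hr$region[hr$hub],
                  intersect(deg_ok, names(which(btw_rank <= 2))))
  # ties at the rank boundary are all included
  expect_equal(hr$betweenness_rank[hr$region %in% c("X", "Y")], c(1L, 1L))
})

test_that("printed qualified lists intersect to the reported hub sets", {
  mptp_deg <- c("AcbC", "CA1", "CA3", "PHA", "VA", "AcbSh", "DMS", "CM", "PFC")
  mptp_btw <- c("PPTg", "SNr", "VTA", "Cg2", "PVN", "Cg1", "Sm", "S1",
                "AcbSh", "Sol")
  expect_equal(hub_overlap(mptp_deg, mptp_btw), "AcbSh")
  acu_deg <- c("PFC", "PVN", "S1", "PPTg", "CM", "Cg2", "PHA", "LC", "AcbC",
               "M1", "VTA", "Cg1", "VL", "CA3", "SNr", "AHA", "DG", "Sm")
  acu_btw <- c("CA3", "PHA", "VL", "IC", "LC", "M1", "DG", "VTA", "Cg1", "CA2")
  ov <- hub_overlap(acu_deg, acu_btw)
  expect_length(ov, 8)
  expect_setequal(ov, c("M1", "DG", "CA3", "Cg1", "PHA", "VL", "VTA", "LC"))
  expect_length(hub_overlap(c("A", "B"), c("C", "D")), 0)
})

test_that("motor subnetwork restricts, thresholds and validates", {
  for (nm in c("naive_motor_9edges", "mptp_motor_3edges", "acu_motor_7edges")) {
    scen <- make_recovery_scenario(nm)
    net <- fosnet:::corr_network(scen$group, MOTOR_REGIONS, scen$truth,
                                 "pearson", 6)
    mg <- motor_subnetwork(net)
    expected <- c(naive_motor_9edges = 9, mptp_motor_3edges = 3,
                  acu_motor_7edges = 7)[[nm]]
    expect_equal(edge_count(mg), expected, info = nm)
    expect_setequal(igraph::V(mg$graph)$name, MOTOR_REGIONS)
  }
  mptp <- make_recovery_scenario("mptp_motor_3edges")
  mg <- motor_subnetwork(fosnet:::corr_network("MPTP", MOTOR_REGIONS,
                                               mptp$truth, "pearson", 6))
  el <- igraph::as_data_frame(mg$graph, what = "edges")
  expect_true(any((el$from == "M1" & el$to == "DLS") |
                  (el$from == "DLS" & el$to == "M1")))
  # all-zero matrix: 0 edges, 7 nodes
  Z <- diag(7); dimnames(Z) <- list(MOTOR_REGIONS, MOTOR_REGIONS)
  gz <- motor_subnetwork(fosnet:::corr_network("g", MOTOR_REGIONS, Z,
                                               "pearson", 6))
  expect_equal(edge_count(gz), 0)
  expect_equal(igraph::vcount(gz$graph), 7)
  # missing motor region is named
  sub <- fosnet:::corr_network("g", c("M1", "DLS"),
                               diag(2), "pearson", 6)
  expect_error(motor_subnetwork(sub), "Gp")
})

test_that("ego network induces center + neighbors with full-graph annotations", {
  # isolated center: single node, no edges
  iso <- graph_fixture(c("M1", "A", "B"),
                       data.frame(from = "A", to = "B", weight = 0.9))
  eg <- ego_network(iso, "M1")
  expect_equal(igraph::vcount(eg$graph), 1)
  expect_equal(edge_count(eg), 0)
  # star centered at M1: ego graph is the whole star
  star <- graph_fixture(c("M1", paste0("l", 1:4)),
                        data.frame(from = "M1", to = paste0("l", 1:4),
                                   weight = 1))
  eg2 <- ego_network(star, "M1")
  expect_equal(igraph::vcount(eg2$graph), 5)
  expect_equal(edge_count(eg2), 4)
  expect_equal(igraph::vertex_attr(eg2$graph, "betweenness")[
    igraph::V(eg2$graph)$name == "M1"], 6)
  # edge betweenness matches exhaustive enumeration on a random graph,
  # and is computed on the full graph before induction
  set.seed(8)
  nodes <- paste0("n", 1:10)
  cmb <- t(combn(nodes, 2))
  keep <- runif(nrow(cmb)) < 0.3
  g <- graph_fixture(nodes, data.frame(from = cmb[keep, 1],
                                       to = cmb[keep, 2], weight = 1))
  center <- nodes[which.max(degree_centrality(g))]
  eg3 <- ego_network(g, center)
  eb_oracle <- brute_edge_betweenness(g$graph)
  el <- igraph::as_data_frame(eg3$graph, what = "edges")
  key <- paste(pmin(el$from, el$to), pmax(el$from, el$to))
  expect_equal(el$edge_betweenness, unname(eb_oracle[key]), tolerance = 1e-10)
  expect_error(ego_network(g, "nope"), "unknown center")
})

test_that("edge counts and degrees are monotone in the threshold", {
  set.seed(12)
  scen <- make_recovery_scenario("acu_motor_7edges")
  co <- suppressWarnings(generate_cohort(scen$summary, 50, scen$corr_specs,
                                         seed = 12, groups = "Acu"))
  net <- interregional_correlation(co, "Acu")
  taus <- c(0.2, 0.35, 0.5, 0.65, 0.8)
  counts <- sapply(taus, function(t) edge_count(threshold_network(net, t)))
  expect_true(all(diff(counts) <= 0))
  degs <- sapply(taus, function(t)
    degree_centrality(threshold_network(net, t)))
  expect_true(all(apply(degs, 1, function(d) all(diff(d) <= 0))))
})

test_that("relabeling region order permutes but does not change results", {
  set.seed(14)
  s <- tiny_summary(c("M1", "DLS", "DMS", "Gp"), "Naive", mean = 20, sem = 2)
  R <- diag(4); R[1, 2] <- R[2, 1] <- 0.8; R[3, 4] <- R[4, 3] <- 0.75
  spec <- correlation_spec("Naive", c("M1", "DLS", "DMS", "Gp"), R)
  co <- generate_cohort(s, 30, list(spec), seed = 14)
  perm <- c("Gp", "M1", "DMS", "DLS")
  net1 <- interregional_correlation(co, "Naive")
  net2 <- interregional_correlation(co, "Naive", regions = perm)
  expect_equal(net2$weight[perm, perm], net1$weight[perm, perm])
  h1 <- identify_hubs(threshold_network(net1, 0.6), degree_min = 1)
  h2 <- identify_hubs(threshold_network(net2, 0.6), degree_min = 1)
  h2 <- h2[match(h1$region, h2$region), ]
  rownames(h1) <- rownames(h2) <- NULL
  expect_equal(h1, h2)
})

test_that("planted motor edge sets are recovered reliably at n = 1000", {
  # detection margin >= 0.1 at n = 1000 makes exact recovery near-certain
  for (nm in c("naive_motor_9edges", "mptp_motor_3edges")) {
    scen <- make_recovery_scenario(nm)
    truth_edges <- which(scen$truth > 0.5 & upper.tri(scen$truth))
    hits <- 0L
    n_runs <- 100
    for (i in seq_len(n_runs)) {
      co <- suppressWarnings(generate_cohort(scen$summary, 1000,
                                             scen$corr_specs, seed = 5000 + i,
                                             groups = scen$group))
      net <- interregional_correlation(co, scen$group)
      found <- which(net$weight > 0.5 & upper.tri(net$weight))
      if (identical(found, truth_edges)) hits <- hits + 1L
    }
    expect_gte(hits / n_runs, 0.95)
  }
})

test_that("small-cohort recovery rate is measurably below large-n recovery", {
  # at the study's n = 6 the same planted structure is often missed;
  # the rate is reported rather than asserted high
  scen <- make_recovery_scenario("naive_motor_9edges")
  truth_edges <- which(scen$truth > 0.5 & upper.tri(scen$truth))
  hits <- 0L
  for (i in 1:50) {
    co <- suppressWarnings(generate_cohort(scen$summary, 6, scen$corr_specs,
                                           seed = 9000 + i,
                                           groups = scen$group))
    net <- interregional_correlation(co, scen$group)
    found <- which(net$weight > 0.5 & upper.tri(net$weight))
    if (identical(found, truth_edges)) hits <- hits + 1L
  }
  rate <- hits / 50
  expect_lt(rate, 0.95)
})

test_that("task PLS is deterministic, symmetric for duplicates, null-calibrated", {
  s <- tiny_summary(paste0("R", 1:6), c("Naive", "MPTP"), mean = 20, sem = 2)
  co <- generate_cohort(s, 8, seed = 55)
  res1 <- pls_lv_correlation(co, n_perm = 100, n_boot = 100, seed = 2)
  res2 <- pls_lv_correlation(co, n_perm = 100, n_boot = 100, seed = 2)
  expect_identical(res1$pls, res2$pls)
  expect_equal(res1$network$method, "pls_lv")
  expect_true(all(diff(res1$pls$singular_values) <= 1e-12))
  expect_true(all(res1$pls$perm_p >= 0 & res1$pls$perm_p <= 1))
  # duplicated region columns: equal bootstrap ratios, derived r = 1
  co_dup <- co
  co_dup$R6 <- co_dup$R1
  res_d <- pls_lv_correlation(co_dup, n_perm = 100, n_boot = 100, seed = 3)
  expect_equal(res_d$pls$bootstrap_ratio["R6", ],
               res_d$pls$bootstrap_ratio["R1", ], tolerance = 1e-8)
  expect_equal(res_d$network$weight["R1", "R6"], 1.0, tolerance = 1e-10)
  # LV truncation warning
  expect_warning(pls_lv_correlation(co, n_perm = 100, n_boot = 100, seed = 2,
                                    n_lv = 5), "rank")
  # null calibration: with identical group means (no group structure at
  # all) LV1 is rarely "significant" under the permutation test
  null_sum <- tiny_summary(paste0("R", 1:30), DEFAULT_GROUPS,
                           mean = 20, sem = 2)
  nonsig <- 0L
  for (i in 1:50) {
    con <- suppressWarnings(generate_cohort(null_sum, 6, seed = 300 + i))
    res <- pls_lv_correlation(con, n_perm = 500, n_boot = 100, seed = i)
    if (res$pls$perm_p[1] > 0.05) nonsig <- nonsig + 1L
  }
  expect_gte(nonsig / 50, 0.9)
})

test_that("pearson and PLS backends agree in sign on strong planted edges", {
  scen <- make_recovery_scenario("naive_motor_9edges")
  co <- suppressWarnings(generate_cohort(scen$summary, 200, scen$corr_specs,
                                         seed = 60))
  net_p <- interregional_correlation(co, "Naive")
  res <- pls_lv_correlation(co[co$group %in% c("Naive", "MPTP"), ],
                            n_perm = 100, n_boot = 100, seed = 4)
  supra <- which(net_p$weight > 0.5 & upper.tri(net_p$weight))
  expect_true(all(sign(res$network$weight[supra]) ==
                  sign(net_p$weight[supra])))
})
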