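# Small programmatic fixtures shared across test files.

# cohort with explicit per-region values; one row per animal
tiny_cohort <- function(activity, group = "Naive") {
  df <- data.frame(animal_id = sprintf("a%02d", seq_len(nrow(activity))),
                   group = group, activity, check.names = FALSE,
                   stringsAsFactors = FALSE)
  class(df) <- c("cohort_matrix", "data.frame")
  df
}

# two-group summary with given means/sems, n per group
tiny_summary <- function(regions = c("M1", "DLS"),
                         groups = c("Naive", "MPTP"),
                         mean = 20, sem = 1, n = 6) {
  p <- length(regions); g <- length(groups)
  mn <- matrix(mean, p, g, dimnames = list(regions, groups))
  sm <- matrix(sem, p, g, dimnames = list(regions, groups))
  info <- data.frame(region = regions, full_name = regions,
                     subdivision = rep(SUBDIVISIONS, length.out = p),
                     stringsAsFactors = FALSE)
  group_summary(info, mn, sm, stats::setNames(rep(n, g), groups))
}

# planted-signal cohort for the prediction stage: rotarod driven by
# th_sn > th_st > M1 with decreasing standardized weights
planted_ml_cohort <- function(n, seed, noise_sd = 20) {
  set.seed(seed)
  co <- tiny_cohort(matrix(rnorm(n * 3, 20, 3), n, 3,
                           dimnames = list(NULL, c("M1", "DG", "Cg1"))))
  co$th_sn <- rnorm(n, 50, 10)
  co$th_st <- rnorm(n, 30, 8)
  z <- function(x) (x - mean(x)) / sd(x)
  co$rotarod_s <- pmin(pmax(
    240 + 10 * z(co$th_sn) + 6 * z(co$th_st) + 3 * z(co$M1) +
      rnorm(n, 0, noise_sd), 0), 480)
  co
}

# build a thresh_graph directly from an edge list over named nodes
graph_fixture <- function(nodes, edges = NULL, tau = 0.5, mode = "signed") {
  if (is.null(edges) || nrow(edges) == 0) {
    g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(nodes)
  } else {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(name = nodes))
  }
  structure(list(graph = g, tau = tau, mode = mode, group = "test",
                 n_missing = 0), class = "thresh_graph")
}

# independent all-pairs shortest-path betweenness by explicit path
# enumeration (exponential; for <= 12-node graphs only)
brute_betweenness <- function(g) {
  nodes <- igraph::V(g)$name
  btw <- stats::setNames(numeric(length(nodes)), nodes)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  all_paths <- function(from, to) {
    # enumerate all simple paths, keep the shortest ones
    res <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == to) { res[[length(res) + 1]] <<- path; return() }
      for (nxt in nodes[adj[last, ]])
        if (!nxt %in% path) walk(c(path, nxt))
    }
    walk(from)
    if (!length(res)) return(list())
    lens <- lengths(res)
    res[lens == min(lens)]
  }
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i >= j) next
    sp <- all_paths(nodes[i], nodes[j])
    if (!length(sp)) next
    for (p in sp) {
      inner <- setdiff(p, c(nodes[i], nodes[j]))
      btw[inner] <- btw[inner] + 1 / length(sp)
    }
  }
  btw
}

# same enumeration, accumulated on edges
brute_edge_betweenness <- function(g) {
  nodes <- igraph::V(g)$name
  el <- igraph::as_data_frame(g, what = "edges")
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  eb <- stats::setNames(numeric(nrow(el)), key(el$from, el$to))
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i >= j) next
    res <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == nodes[j]) { res[[length(res) + 1]] <<- path; return() }
      for (nxt in nodes[adj[last, ]])
        if (!nxt %in% path) walk(c(path, nxt))
    }
    walk(nodes[i])
    if (!length(res)) next
    lens <- lengths(res)
    sp <- res[lens == min(lens)]
    for (p in sp)
      for (e in seq_len(length(p) - 1))
        eb[key(p[e], p[e + 1])] <- eb[key(p[e], p[e + 1])] + 1 / length(sp)
  }
  eb
}
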