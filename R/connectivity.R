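# Per-group interregional correlation networks, thresholded graphs,
# centralities, hubs, and motor / seed-centered subnetworks.
#
# Edges are cross-animal correlations of regional c-Fos counts within one
# group. Thresholding keeps signed r > tau by default (absolute mode is a
# flag); all regions stay as nodes even when isolated, so a disconnected
# region is visible rather than silently dropped.

#' Build the interregional correlation network for one group
#'
#' Correlates every pair of region columns across the animals of one group.
#' Zero-variance regions give missing weights (with a warning naming the
#' region), never 0.
#'
#' @param cohort cohort data.frame.
#' @param group group label (>= 3 animals).
#' @param method `"pearson"` or `"spearman"`.
#' @param regions region subset; default all region columns.
#' @return A `corr_network`: list with `group`, `regions`, symmetric `weight`
#'   matrix, `method`, `n_animals`.
#' @export
interregional_correlation <- function(cohort, group,
                                      method = c("pearson", "spearman"),
                                      regions = NULL) {
  method <- match.arg(method)
  rows <- cohort$group == group
  if (sum(rows) < 3)
    stop("group '", group, "' has ", sum(rows), " animals; need >= 3")
  if (is.null(regions)) regions <- cohort_regions(cohort)
  X <- as.matrix(cohort[rows, regions, drop = FALSE])
  flat <- regions[apply(X, 2, stats::sd) == 0]
  if (length(flat))
    warning("zero-variance region(s) in group '", group, "': ",
            paste(flat, collapse = ", "), "; their correlations are missing")
  W <- suppressWarnings(stats::cor(X, method = method))
  W[flat, ] <- NA_real_; W[, flat] <- NA_real_
  diag(W) <- 1
  corr_network(group, regions, W, method, sum(rows))
}

corr_network <- function(group, regions, weight, method, n_animals) {
  dimnames(weight) <- list(regions, regions)
  structure(list(group = group, regions = regions, weight = weight,
                 method = method, n_animals = n_animals),
            class = "corr_network")
}

#' @export
print.corr_network <- function(x, ...) {
  cat("<corr_network> group=", x$group, ", ", length(x$regions),
      " regions, method=", x$method, ", n=", x$n_animals, "\n", sep = "")
  invisible(x)
}

#' Threshold a correlation network into a graph
#'
#' Keeps edges with weight strictly greater than `tau` (signed mode) or
#' `|weight| > tau` (absolute mode). Every region remains a node; missing
#' weights are skipped and counted.
#'
#' @param network a `corr_network`.
#' @param tau threshold in (0, 1). The whole-brain analysis uses 0.6; the
#'   motor subnetwork uses 0.5.
#' @param mode `"signed"` (default) or `"absolute"`.
#' @param subdivisions optional named vector region -> subdivision attached
#'   as a node attribute.
#' @return A `thresh_graph`: list with the igraph `graph`, `tau`, `mode`,
#'   and `n_missing` (weight pairs skipped as missing).
#' @export
threshold_network <- function(network, tau, mode = c("signed", "absolute"),
                              subdivisions = NULL) {
  stopifnot(inherits(network, "corr_network"), tau > 0, tau < 1)
  mode <- match.arg(mode)
  W <- network$weight
  ut <- upper.tri(W)
  n_missing <- sum(is.na(W[ut]))
  keep <- ut & !is.na(W) & (if (mode == "signed") W > tau else abs(W) > tau)
  idx <- which(keep, arr.ind = TRUE)
  el <- data.frame(from = network$regions[idx[, 1]],
                   to = network$regions[idx[, 2]],
                   weight = W[keep], stringsAsFactors = FALSE)
  vertices <- data.frame(name = network$regions, stringsAsFactors = FALSE)
  if (!is.null(subdivisions))
    vertices$subdivision <- unname(subdivisions[network$regions])
  g <- igraph::graph_from_data_frame(el, directed = FALSE, vertices = vertices)
  structure(list(graph = g, tau = tau, mode = mode, group = network$group,
                 n_missing = n_missing),
            class = "thresh_graph")
}

#' @export
print.thresh_graph <- function(x, ...) {
  cat("<thresh_graph> ", igraph::vcount(x$graph), " nodes, ",
      igraph::ecount(x$graph), " edges (tau=", x$tau, ", ", x$mode, ")\n",
      sep = "")
  invisible(x)
}

#' Number of edges in a thresholded graph
#' @param graph a `thresh_graph` or igraph.
#' @return Integer edge count.
#' @export
edge_count <- function(graph) igraph::ecount(as_igraph(graph))

#' Node degree in a thresholded graph
#'
#' Default is the binary count of incident supra-threshold edges — hub
#' qualification ("a score of 5 or greater") implies integer counts. The
#' strength variant sums incident absolute edge weights.
#'
#' @param graph a `thresh_graph` or igraph.
#' @param weighted if `TRUE`, return strength (sum of |weights|) instead of
#'   the binary count.
#' @return Named numeric vector over all nodes.
#' @export
degree_centrality <- function(graph, weighted = FALSE) {
  g <- as_igraph(graph)
  if (weighted && igraph::ecount(g) > 0 &&
      "weight" %in% igraph::edge_attr_names(g))
    return(igraph::strength(g, weights = abs(igraph::E(g)$weight)))
  igraph::degree(g)
}

#' Shortest-path betweenness centrality
#'
#' Unnormalized node betweenness on the binarized (unit-length-edge) graph:
#' for each unordered pair of other nodes, the fraction of shortest paths
#' through the node, summed over pairs. Pairs in different components
#' contribute 0. A `1 - r` edge-length variant is available for users who
#' want strong correlations to act as short distances.
#'
#' @param graph a `thresh_graph` or igraph.
#' @param weighted if `TRUE`, use `1 - weight` as edge length.
#' @return Named numeric vector over all nodes.
#' @export
betweenness_centrality <- function(graph, weighted = FALSE) {
  g <- as_igraph(graph)
  w <- NULL
  if (weighted && igraph::ecount(g) > 0) w <- 1 - igraph::E(g)$weight
  igraph::betweenness(g, directed = FALSE, weights = w, normalized = FALSE)
}

descending_min_rank <- function(x) {
  # ties share the smallest (best) rank: values 5,5,3 -> ranks 1,1,3
  rank(-x, ties.method = "min")
}

#' Identify hub regions by joint degree and betweenness criteria
#'
#' A region qualifies on degree when its binary degree is at least
#' `degree_min` (default 5) and on betweenness when its descending
#' betweenness rank is within `betweenness_top_k` (default 10, i.e. the top
#' third of a 30-region set). Ties at the rank boundary are all included.
#' A hub satisfies both.
#'
#' @param graph a `thresh_graph` or igraph.
#' @param degree_min minimum degree score (default 5).
#' @param betweenness_top_k betweenness rank cutoff (default 10).
#' @return A `hub_report` data.frame: region, degree, betweenness,
#'   degree_rank, betweenness_rank, degree_qualified, betweenness_qualified,
#'   hub.
#' @export
identify_hubs <- function(graph, degree_min = 5, betweenness_top_k = 10) {
  g <- as_igraph(graph)
  if (igraph::vcount(g) < 1) stop("graph has no nodes")
  deg <- degree_centrality(g)
  btw <- betweenness_centrality(g)
  rep <- data.frame(
    region = igraph::V(g)$name,
    degree = as.integer(deg),
    betweenness = unname(btw),
    degree_rank = descending_min_rank(deg),
    betweenness_rank = descending_min_rank(btw),
    stringsAsFactors = FALSE)
  rep$degree_qualified <- rep$degree >= degree_min
  # ties at the rank boundary are all included (min rank shared across ties)
  rep$betweenness_qualified <- rep$betweenness_rank <= betweenness_top_k
  rep$hub <- rep$degree_qualified & rep$betweenness_qualified
  class(rep) <- c("hub_report", "data.frame")
  rep
}

#' Overlap of degree-qualified and betweenness-qualified regions
#'
#' The Venn-intersection step of hub identification: regions present in both
#' ranked lists.
#'
#' @param degree_qualified,betweenness_qualified character vectors of region
#'   abbreviations.
#' @return Character vector (order of `degree_qualified` preserved).
#' @export
hub_overlap <- function(degree_qualified, betweenness_qualified) {
  intersect(degree_qualified, betweenness_qualified)
}

#' Motor-circuit subnetwork
#'
#' Restricts a correlation network to the seven motor-related regions
#' ([MOTOR_REGIONS]) and thresholds at `tau` (signed mode, default 0.5).
#'
#' @param network a `corr_network` containing all seven motor regions.
#' @param tau threshold (default 0.5).
#' @return A `thresh_graph` over the seven motor regions.
#' @export
motor_subnetwork <- function(network, tau = 0.5) {
  stopifnot(inherits(network, "corr_network"))
  missing <- setdiff(MOTOR_REGIONS, network$regions)
  if (length(missing))
    stop("motor region(s) missing from network: ",
         paste(missing, collapse = ", "))
  sub <- corr_network(network$group, MOTOR_REGIONS,
                      network$weight[MOTOR_REGIONS, MOTOR_REGIONS],
                      network$method, network$n_animals)
  threshold_network(sub, tau, mode = "signed")
}

#' Seed-centered (ego) network
#'
#' Subgraph induced by a seed region and its direct neighbors, annotated with
#' node betweenness and edge betweenness computed on the full graph (so the
#' annotations reflect each element's role in the whole network, not just the
#' ego neighborhood).
#'
#' @param graph a `thresh_graph`.
#' @param center seed region (default `"M1"`, primary motor cortex).
#' @return A `thresh_graph` whose igraph carries `betweenness` node and
#'   `edge_betweenness` edge attributes.
#' @export
ego_network <- function(graph, center = "M1") {
  stopifnot(inherits(graph, "thresh_graph"))
  g <- graph$graph
  if (!center %in% igraph::V(g)$name)
    stop("unknown center region '", center, "'")
  btw <- betweenness_centrality(g)
  ebtw <- if (igraph::ecount(g) > 0)
    igraph::edge_betweenness(g, directed = FALSE, weights = NA) else numeric(0)
  g <- igraph::set_vertex_attr(g, "betweenness", value = unname(btw))
  if (igraph::ecount(g) > 0)
    g <- igraph::set_edge_attr(g, "edge_betweenness", value = ebtw)
  keep <- c(center, igraph::neighbors(g, center)$name)
  ego <- igraph::induced_subgraph(g, keep)
  structure(list(graph = ego, tau = graph$tau, mode = graph$mode,
                 group = graph$group, center = center),
            class = "thresh_graph")
}

#' Annotate a thresholded graph with centralities and hub flags
#'
#' Attaches degree, betweenness and the hub flag from [identify_hubs()] as
#' node attributes, ready for [write_network()] export.
#'
#' @param graph a `thresh_graph`.
#' @param degree_min,betweenness_top_k hub criteria, as in [identify_hubs()].
#' @return The `thresh_graph` with annotated igraph.
#' @export
annotate_graph <- function(graph, degree_min = 5, betweenness_top_k = 10) {
  stopifnot(inherits(graph, "thresh_graph"))
  hubs <- identify_hubs(graph, degree_min, betweenness_top_k)
  g <- graph$graph
  g <- igraph::set_vertex_attr(g, "degree", value = hubs$degree)
  g <- igraph::set_vertex_attr(g, "betweenness", value = hubs$betweenness)
  g <- igraph::set_vertex_attr(g, "hub", value = as.numeric(hubs$hub))
  graph$graph <- g
  graph
}

# ---- task PLS backend ------------------------------------------------------

#' Mean-centered task PLS of regional activity against group structure
#'
#' Singular value decomposition of the group-mean deviation matrix (group
#' means minus the grand mean, animals weighted equally within group). Each
#' latent variable (LV) pairs a group contrast with a regional salience
#' pattern. LV significance is assessed by permuting group labels; salience
#' stability by bootstrap resampling of animals within groups (bootstrap
#' ratio = original salience / bootstrap SE). The derived network correlates
#' each region's LV-adjusted activity profile — per-animal activity with the
#' group-mean component captured by the retained LVs removed, standardized
#' within group — so it reflects interregional co-fluctuation around the
#' group structure the LVs encode (approximately the n-weighted average of
#' the within-group correlations). Tagged `method = "pls_lv"`.
#'
#' @param cohort cohort data.frame (>= 2 groups).
#' @param n_perm,n_boot resampling iteration counts (>= 100; defaults 1000).
#' @param seed integer seed.
#' @param n_lv LVs to retain for the derived network; default all (rank of
#'   the design). Requests beyond the rank are truncated with a warning.
#' @return list with `pls` (a `pls_result`: `singular_values`, `perm_p`,
#'   `brain_saliences`, `design_saliences`, `bootstrap_ratio`) and `network`
#'   (a `corr_network` tagged `pls_lv`).
#' @export
pls_lv_correlation <- function(cohort, n_perm = 1000, n_boot = 1000,
                               seed = 1, n_lv = NULL) {
  stopifnot(n_perm >= 100, n_boot >= 100)
  regions <- cohort_regions(cohort)
  X <- as.matrix(cohort[regions])
  grp <- factor(cohort$group)
  if (nlevels(grp) < 2) stop("need >= 2 groups for task PLS")
  rank_max <- min(nlevels(grp) - 1, length(regions))
  if (is.null(n_lv)) n_lv <- rank_max
  if (n_lv > rank_max) {
    warning("requested ", n_lv, " LVs but design rank is ", rank_max,
            "; truncating")
    n_lv <- rank_max
  }
  mean_dev <- function(X, grp) {
    gm <- rowsum(X, grp) / as.vector(table(grp))
    sweep(gm, 2, colMeans(gm))
  }
  sv_of <- function(X, grp) svd(mean_dev(X, grp))
  dec <- sv_of(X, grp)
  k <- rank_max
  sv <- dec$d[seq_len(k)]
  V <- dec$v[, seq_len(k), drop = FALSE]      # brain saliences
  U <- dec$u[, seq_len(k), drop = FALSE]      # design saliences
  rownames(V) <- regions
  rownames(U) <- levels(grp)

  set.seed(seed)
  # permutation test: shuffle group labels, compare singular values
  perm_ge <- numeric(k)
  for (b in seq_len(n_perm)) {
    d_p <- svd(mean_dev(X, sample(grp)))$d[seq_len(k)]
    perm_ge <- perm_ge + (d_p >= sv)
  }
  perm_p <- (perm_ge + 1) / (n_perm + 1)

  # bootstrap: resample animals within groups, align salience signs to the
  # original solution before accumulating
  boot_sum <- boot_sq <- matrix(0, length(regions), k)
  idx_by_group <- split(seq_len(nrow(X)), grp)
  for (b in seq_len(n_boot)) {
    take <- unlist(lapply(idx_by_group, function(ii)
      ii[sample.int(length(ii), length(ii), replace = TRUE)]))
    dec_b <- svd(mean_dev(X[take, , drop = FALSE], grp[take]))
    Vb <- dec_b$v[, seq_len(k), drop = FALSE]
    sgn <- sign(colSums(Vb * V)); sgn[sgn == 0] <- 1
    Vb <- sweep(Vb, 2, sgn, `*`)
    boot_sum <- boot_sum + Vb
    boot_sq <- boot_sq + Vb^2
  }
  boot_se <- sqrt(pmax(boot_sq / n_boot - (boot_sum / n_boot)^2, 0))
  bsr <- V / boot_se
  bsr[boot_se == 0] <- NA_real_
  dimnames(bsr) <- list(regions, paste0("LV", seq_len(k)))

  # derived network: remove from each animal's profile the group-mean
  # component reconstructed from the retained LVs, standardize the residual
  # within group (groups differ widely in dispersion), then correlate regions
  Vk <- V[, seq_len(n_lv), drop = FALSE]
  gm_hat <- (U[, seq_len(n_lv), drop = FALSE] %*%
               (sv[seq_len(n_lv)] * t(Vk)))[as.integer(grp), , drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  Xp <- Xc - gm_hat
  for (g in levels(grp)) {
    rows <- grp == g
    sds <- apply(Xp[rows, , drop = FALSE], 2, stats::sd)
    sds[sds == 0] <- 1
    Xp[rows, ] <- sweep(Xp[rows, , drop = FALSE], 2, sds, `/`)
  }
  flat <- apply(Xp, 2, stats::sd) == 0
  W <- suppressWarnings(stats::cor(Xp))
  W[flat, ] <- NA_real_; W[, flat] <- NA_real_
  diag(W) <- 1
  pls <- structure(list(singular_values = sv, perm_p = perm_p,
                        brain_saliences = V, design_saliences = U,
                        bootstrap_ratio = bsr, n_lv = n_lv,
                        n_perm = n_perm, n_boot = n_boot, seed = seed),
                   class = "pls_result")
  list(pls = pls,
       network = corr_network("all", regions, W, "pls_lv", nrow(X)))
}
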