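# Domain containers and delimited-text readers/writers.
#
# Region abbreviations are the canonical join key everywhere; full names are
# display-only. Group labels are configurable but default to the study's four
# arms and are compared case-sensitively.

#' Construct a group summary table
#'
#' A `group_summary` holds per-region, per-group mean and SEM of c-Fos counts
#' (cells per counting frame) together with the number of animals per group.
#' It is the in-memory form of a printed summary table and the calibration
#' input of [generate_cohort()].
#'
#' @param regions data.frame with columns `region`, `full_name`, `subdivision`.
#' @param mean,sem numeric matrices, regions x groups, dimnames set.
#' @param n named integer vector of animals per group.
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(regions, mean, sem, n) {
  stopifnot(is.data.frame(regions),
            all(c("region", "full_name", "subdivision") %in% names(regions)))
  if (anyDuplicated(regions$region))
    stop("duplicate region abbreviation: ",
         paste(unique(regions$region[duplicated(regions$region)]), collapse = ", "))
  bad_sub <- setdiff(unique(regions$subdivision), SUBDIVISIONS)
  if (length(bad_sub))
    stop("unknown subdivision(s): ", paste(bad_sub, collapse = ", "),
         " (expected one of: ", paste(SUBDIVISIONS, collapse = ", "), ")")
  mean <- as.matrix(mean); sem <- as.matrix(sem)
  groups <- colnames(mean)
  stopifnot(identical(dim(mean), dim(sem)),
            identical(rownames(mean), regions$region),
            identical(colnames(sem), groups))
  check_cells <- function(m, what) {
    bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
    if (nrow(bad))
      stop("invalid ", what, " for region '", rownames(m)[bad[1, 1]],
           "', group '", colnames(m)[bad[1, 2]], "' (row ", bad[1, 1],
           "): must be a non-negative number")
  }
  check_cells(mean, "mean"); check_cells(sem, "SEM")
  n <- n[groups]
  if (any(is.na(n)) || any(n < 2))
    stop("every group needs n >= 2 animals; got: ",
         paste(names(n), n, sep = "=", collapse = ", "))
  structure(list(regions = regions, groups = groups,
                 mean = mean, sem = sem, n = n),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("<group_summary> ", nrow(x$mean), " regions x ", length(x$groups),
      " groups (", paste(x$groups, x$n, sep = " n=", collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Restrict a group summary to a subset of regions
#'
#' @param summary a [group_summary()].
#' @param regions character vector of abbreviations to keep (order preserved).
#' @return A `group_summary` over the requested regions.
#' @export
subset_summary <- function(summary, regions) {
  stopifnot(inherits(summary, "group_summary"))
  missing <- setdiff(regions, summary$regions$region)
  if (length(missing))
    stop("region(s) not in summary: ", paste(missing, collapse = ", "))
  idx <- match(regions, summary$regions$region)
  group_summary(summary$regions[idx, , drop = FALSE],
                summary$mean[idx, , drop = FALSE],
                summary$sem[idx, , drop = FALSE],
                summary$n)
}

#' Read a group summary table from CSV
#'
#' Expects columns `region`, `full_name`, `subdivision`, then one
#' `<group>_mean` / `<group>_sem` pair per group. Animals per group are read
#' from a JSON sidecar (`{"Naive": 6, ...}`) found at `sub("\\.csv$", "_n.json",
#' path)` unless `n` is given directly.
#'
#' @param path CSV file path.
#' @param n optional named integer vector of animals per group; overrides the
#'   sidecar.
#' @return A [group_summary()].
#' @export
load_group_summary <- function(path, n = NULL) {
  if (!file.exists(path)) stop("summary file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("region", "full_name", "subdivision"))
    if (!col %in% names(df)) stop("summary file is missing column '", col, "'")
  mean_cols <- grep("_mean$", names(df), value = TRUE)
  if (!length(mean_cols)) stop("summary file is missing column '<group>_mean'")
  groups <- sub("_mean$", "", mean_cols)
  sem_cols <- paste0(groups, "_sem")
  absent <- setdiff(sem_cols, names(df))
  if (length(absent))
    stop("summary file is missing column '", absent[1], "'")
  if (is.null(n)) {
    sidecar <- sub("\\.csv$", "_n.json", path)
    if (!file.exists(sidecar))
      stop("no per-group n: sidecar ", sidecar, " not found and `n` not given")
    n <- unlist(jsonlite::read_json(sidecar))
  }
  blank <- function(cols, what) {
    for (g in seq_along(groups)) {
      v <- df[[cols[g]]]
      if (any(is.na(v)))
        stop("blank ", what, " for region '", df$region[which(is.na(v))[1]],
             "', group '", groups[g], "'")
    }
  }
  blank(mean_cols, "mean"); blank(sem_cols, "SEM")
  mk <- function(cols) {
    m <- as.matrix(df[cols]); dimnames(m) <- list(df$region, groups); m
  }
  group_summary(df[c("region", "full_name", "subdivision")],
                mk(mean_cols), mk(sem_cols), n)
}

#' Write a group summary table (and its n sidecar) to CSV
#'
#' @param summary a [group_summary()].
#' @param path output CSV path; the per-group n go to `sub("\\.csv$",
#'   "_n.json", path)`.
#' @return `path`, invisibly.
#' @export
write_group_summary <- function(summary, path) {
  stopifnot(inherits(summary, "group_summary"))
  df <- summary$regions
  for (g in summary$groups) {
    df[[paste0(g, "_mean")]] <- summary$mean[, g]
    df[[paste0(g, "_sem")]] <- summary$sem[, g]
  }
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(as.list(summary$n), sub("\\.csv$", "_n.json", path),
                       auto_unbox = TRUE)
  invisible(path)
}

#' The packaged 30-region, 4-group c-Fos summary fixture
#'
#' Mean and SEM of c-Fos-positive cells per counting frame in 30 brain
#' regions for the four study arms (n = 6 animals per group).
#'
#' @return A [group_summary()] with 30 regions and 4 groups.
#' @export
fosnet_table1 <- function() {
  load_group_summary(system.file("extdata", "cfos_summary_table1.csv",
                                 package = "fosnet", mustWork = TRUE))
}

# ---- cohort tables ---------------------------------------------------------

#' Region columns of a cohort table
#' @param cohort a cohort data.frame as returned by [read_cohort()] or
#'   [generate_cohort()].
#' @return Character vector of region column names.
#' @export
cohort_regions <- function(cohort) {
  setdiff(names(cohort), c("animal_id", "group", BEHAVIOR_COLUMNS))
}

validate_cohort <- function(cohort, groups = NULL) {
  for (col in c("animal_id", "group"))
    if (!col %in% names(cohort)) stop("cohort is missing column '", col, "'")
  dup <- cohort$animal_id[duplicated(cohort$animal_id)]
  if (length(dup)) stop("duplicate animal_id: ", paste(unique(dup), collapse = ", "))
  if (!is.null(groups)) {
    bad <- setdiff(unique(cohort$group), groups)
    if (length(bad))
      stop("group label(s) outside the configured set (",
           paste(groups, collapse = ", "), "): ", paste(bad, collapse = ", "))
  }
  regs <- cohort_regions(cohort)
  if (!length(regs)) stop("cohort has no region columns")
  for (r in regs) {
    v <- cohort[[r]]
    bad <- which(is.finite(v) & v < 0)
    if (length(bad))
      stop("negative activity for region '", r, "' at row ", bad[1])
  }
  if ("rotarod_s" %in% names(cohort)) {
    v <- cohort$rotarod_s
    bad <- which(is.finite(v) & (v < 0 | v > ROTAROD_MAX_S))
    if (length(bad))
      stop("rotarod_s out of range [0, ", ROTAROD_MAX_S, "] at row ", bad[1],
           " (value ", v[bad[1]], ")")
  }
  invisible(cohort)
}

#' Read a per-animal cohort table
#'
#' Wide delimited text: `animal_id`, `group`, one column per region
#' abbreviation, plus optional behavior/TH columns (`rotarod_s`,
#' `cylinder_rearings`, `th_st`, `th_sn`). Missing optional columns are
#' simply absent; they are never imputed.
#'
#' @param path CSV or TSV file (delimiter sniffed from the header line).
#' @param groups allowed group labels (case-sensitive); `NULL` disables the
#'   check.
#' @param known_regions region abbreviations considered valid; defaults to the
#'   packaged 30-region set. Columns outside the set are rejected unless
#'   `allow_unknown_regions = TRUE`.
#' @param allow_unknown_regions keep unrecognised region columns instead of
#'   erroring.
#' @return A data.frame of class `cohort_matrix`.
#' @export
read_cohort <- function(path, groups = DEFAULT_GROUPS, known_regions = NULL,
                        allow_unknown_regions = FALSE) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (is.null(known_regions))
    known_regions <- fosnet_table1()$regions$region
  regs <- cohort_regions(df)
  unknown <- setdiff(regs, known_regions)
  if (length(unknown) && !allow_unknown_regions)
    stop("unknown region column(s): ", paste(unknown, collapse = ", "),
         " (set allow_unknown_regions = TRUE to keep them)")
  validate_cohort(df, groups)
  class(df) <- c("cohort_matrix", "data.frame")
  df
}

#' Write a cohort table to delimited text
#'
#' @param cohort cohort data.frame.
#' @param path output path; `.tsv` extension selects tab delimiting,
#'   anything else comma.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(cohort, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- network export --------------------------------------------------------

#' Export a thresholded graph
#'
#' Persists nodes (with region, subdivision, degree, betweenness and hub
#' attributes when present) and weighted edges. GraphML and GEXF round-trip
#' topology and weights; the TSV edge list keeps `source`, `target`, `weight`
#' only (isolated nodes are listed in a `#` comment header so that read-back
#' restores the full node set).
#'
#' @param graph a `thresh_graph` (see [threshold_network()]) or an igraph.
#' @param path output file path.
#' @param format one of `"graphml"`, `"gexf"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(graph, path, format = c("graphml", "gexf", "tsv")) {
  if (!is.character(format) || !all(format %in% c("graphml", "gexf", "tsv")))
    stop("unsupported format '", format[1],
         "'; supported formats: graphml, gexf, tsv")
  format <- match.arg(format)
  g <- as_igraph(graph)
  switch(format,
    graphml = igraph::write_graph(g, path, format = "graphml"),
    gexf = write_gexf(g, path),
    tsv = {
      el <- igraph::as_data_frame(g, what = "edges")
      el <- el[c("from", "to", intersect("weight", names(el)))]
      names(el)[1:2] <- c("source", "target")
      if (!"weight" %in% names(el)) el$weight <- rep(1, nrow(el))
      con <- file(path, "w")
      on.exit(close(con))
      writeLines(paste0("# nodes: ",
                        paste(igraph::V(g)$name, collapse = ",")), con)
      utils::write.table(el, con, sep = "\t", row.names = FALSE, quote = FALSE)
    })
  invisible(path)
}

#' Read a graph written by [write_network()]
#'
#' @param path file path.
#' @param format as in [write_network()]; guessed from the extension when
#'   missing.
#' @return An igraph object.
#' @export
read_network <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- switch(tools::file_ext(path), graphml = "graphml",
                     gexf = "gexf", tsv = "tsv", "graphml")
  }
  if (!format %in% c("graphml", "gexf", "tsv"))
    stop("unsupported format '", format, "'; supported formats: graphml, gexf, tsv")
  switch(format,
    graphml = igraph::read_graph(path, format = "graphml"),
    gexf = read_gexf(path),
    tsv = {
      header <- readLines(path, n = 1)
      nodes <- strsplit(sub("^# nodes: ", "", header), ",")[[1]]
      el <- utils::read.delim(path, sep = "\t", comment.char = "#",
                              stringsAsFactors = FALSE)
      g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                         vertices = data.frame(name = nodes))
      g
    })
}

as_igraph <- function(graph) {
  if (igraph::is_igraph(graph)) return(graph)
  if (inherits(graph, "thresh_graph")) return(graph$graph)
  stop("cannot interpret object of class ", paste(class(graph), collapse = "/"),
       " as a graph")
}

# Minimal GEXF 1.2 writer/reader (undirected, static, float node/edge attrs).
write_gexf <- function(g, path) {
  doc <- xml2::xml_new_root("gexf",
    xmlns = "http://www.gexf.net/1.2draft", version = "1.2")
  graph_node <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  vattrs <- setdiff(igraph::vertex_attr_names(g), "name")
  if (length(vattrs)) {
    attnode <- xml2::xml_add_child(graph_node, "attributes", class = "node")
    for (i in seq_along(vattrs)) {
      a <- vattrs[i]
      type <- if (is.numeric(igraph::vertex_attr(g, a))) "double" else "string"
      xml2::xml_add_child(attnode, "attribute", id = as.character(i - 1),
                          title = a, type = type)
    }
  }
  nodes <- xml2::xml_add_child(graph_node, "nodes")
  for (v in seq_len(igraph::vcount(g))) {
    nd <- xml2::xml_add_child(nodes, "node",
                              id = igraph::V(g)$name[v],
                              label = igraph::V(g)$name[v])
    if (length(vattrs)) {
      av <- xml2::xml_add_child(nd, "attvalues")
      for (i in seq_along(vattrs)) {
        val <- igraph::vertex_attr(g, vattrs[i], v)
        xml2::xml_add_child(av, "attvalue", `for` = as.character(i - 1),
                            value = format(val, digits = 15))
      }
    }
  }
  edges <- xml2::xml_add_child(graph_node, "edges")
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_data_frame(g, what = "edges")
    w <- if ("weight" %in% names(el)) el$weight else rep(1, nrow(el))
    for (e in seq_len(nrow(el)))
      xml2::xml_add_child(edges, "edge", id = as.character(e - 1),
                          source = el$from[e], target = el$to[e],
                          weight = format(w[e], digits = 15))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

read_gexf <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  attr_defs <- xml2::xml_find_all(doc, ".//g:attributes[@class='node']/g:attribute", ns)
  def <- data.frame(id = xml2::xml_attr(attr_defs, "id"),
                    title = xml2::xml_attr(attr_defs, "title"),
                    type = xml2::xml_attr(attr_defs, "type"),
                    stringsAsFactors = FALSE)
  node_els <- xml2::xml_find_all(doc, ".//g:nodes/g:node", ns)
  vertices <- data.frame(name = xml2::xml_attr(node_els, "id"),
                         stringsAsFactors = FALSE)
  for (k in seq_len(nrow(def))) {
    vals <- vapply(node_els, function(nd) {
      a <- xml2::xml_find_first(nd, paste0(".//g:attvalue[@for='", def$id[k], "']"), ns)
      xml2::xml_attr(a, "value")
    }, character(1))
    vertices[[def$title[k]]] <-
      if (def$type[k] == "double") as.numeric(vals) else vals
  }
  edge_els <- xml2::xml_find_all(doc, ".//g:edges/g:edge", ns)
  el <- data.frame(from = xml2::xml_attr(edge_els, "source"),
                   to = xml2::xml_attr(edge_els, "target"),
                   stringsAsFactors = FALSE)
  w <- xml2::xml_attr(edge_els, "weight")
  if (nrow(el)) el$weight <- as.numeric(w)
  igraph::graph_from_data_frame(el, directed = FALSE, vertices = vertices)
}
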