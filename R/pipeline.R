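# End-to-end orchestration: simulate or load a cohort, run group statistics,
# build per-group networks, identify hubs, extract motor and seed
# subnetworks, optionally fit the behavior predictors, and write a
# machine-readable bundle with a checksum MANIFEST.

#' Assemble a pipeline configuration
#'
#' Collects the analysis constants in one place: the whole-brain threshold
#' (0.6), the motor-subnetwork threshold (0.5), the hub criteria (degree >= 5,
#' betweenness rank <= 10), and the input source — either a cohort file or a
#' named scenario with a simulation size.
#'
#' @param cohort_file path to a cohort table, or `NULL` to simulate.
#' @param scenario scenario name for [make_recovery_scenario()] when
#'   simulating.
#' @param n_per_group simulated animals per group.
#' @param groups group labels.
#' @param method correlation backend, `"pearson"` or `"spearman"`.
#' @param tau_whole whole-brain edge threshold (default 0.6).
#' @param tau_motor motor-subnetwork threshold (default 0.5).
#' @param degree_min,betweenness_top_k hub criteria.
#' @param ego_center seed region for the ego network (default M1).
#' @param ml_target,ml_features behavior-prediction spec; the ML stage runs
#'   only when the target column is present in the cohort.
#' @param out_dir output bundle directory.
#' @param seed integer seed stamped into every artifact.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort_file = NULL, scenario = "whole_brain_null",
                            n_per_group = 6, groups = DEFAULT_GROUPS,
                            method = "pearson", tau_whole = 0.6,
                            tau_motor = 0.5, degree_min = 5,
                            betweenness_top_k = 10, ego_center = "M1",
                            ml_target = "rotarod_s",
                            ml_features = DEFAULT_ML_FEATURES,
                            out_dir = "fosnet_bundle", seed = 1) {
  stopifnot(tau_whole > 0, tau_whole < 1, tau_motor > 0, tau_motor < 1)
  structure(list(cohort_file = cohort_file, scenario = scenario,
                 n_per_group = n_per_group, groups = groups, method = method,
                 tau_whole = tau_whole, tau_motor = tau_motor,
                 degree_min = degree_min,
                 betweenness_top_k = betweenness_top_k,
                 ego_center = ego_center, ml_target = ml_target,
                 ml_features = ml_features, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys as in [pipeline_config()], all optional.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, cfg)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  stable <- config[setdiff(names(config), "out_dir")]
  writeLines(jsonlite::toJSON(stable, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

stamp <- function(path, config) {
  # sidecar provenance stamp per artifact
  jsonlite::write_json(list(seed = config$seed, config = config_hash(config)),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages: input (load or simulate a cohort), per-region group statistics,
#' per-group correlation networks, thresholded whole-brain graphs with hub
#' reports, motor subnetwork, seed-centered ego network, and — when the
#' target behavior column is present — the five-regressor prediction stage.
#' Every artifact is written under `config$out_dir` with a provenance stamp
#' (seed + config hash); a MANIFEST records an md5 checksum per file, so a
#' rerun with the same config is verifiably identical. On stage failure a
#' partial MANIFEST is written with an `incomplete` marker naming the stage.
#'
#' @param config a `pipeline_config`.
#' @return Invisibly, a list with the in-memory results (`cohort`, `stats`,
#'   `networks`, `graphs`, `hubs`, `motor`, `ego`, `ml`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  add <- function(path) files <<- c(files, path)
  stage <- "input"
  result <- list()
  ok <- tryCatch({
    if (!is.null(config$cohort_file)) {
      cohort <- read_cohort(config$cohort_file, groups = config$groups)
    } else {
      scen <- make_recovery_scenario(config$scenario)
      cohort <- suppressWarnings(generate_cohort(
        scen$summary, config$n_per_group, scen$corr_specs, seed = config$seed))
    }
    message("stage input: ", nrow(cohort), " animals x ",
            length(cohort_regions(cohort)), " regions")
    f <- file.path(config$out_dir, "cohort.csv")
    write_cohort(cohort, f); add(stamp(f, config))
    result$cohort <- cohort

    stage <- "group_stats"
    stats_out <- region_group_stats(cohort)
    f <- file.path(config$out_dir, "anova.csv")
    utils::write.csv(stats_out$anova, f, row.names = FALSE); add(stamp(f, config))
    f <- file.path(config$out_dir, "tukey.csv")
    utils::write.csv(stats_out$tukey, f, row.names = FALSE); add(stamp(f, config))
    result$stats <- stats_out

    stage <- "networks"
    groups_present <- intersect(config$groups, unique(cohort$group))
    networks <- graphs <- hubs <- motor <- ego <- list()
    for (g in groups_present) {
      net <- interregional_correlation(cohort, g, method = config$method)
      networks[[g]] <- net
      f <- file.path(config$out_dir, paste0("correlation_", g, ".csv"))
      utils::write.csv(net$weight, f); add(stamp(f, config))

      gr <- threshold_network(net, config$tau_whole)
      gr <- annotate_graph(gr, config$degree_min, config$betweenness_top_k)
      graphs[[g]] <- gr
      f <- file.path(config$out_dir, paste0("network_", g, ".graphml"))
      write_network(gr, f, "graphml"); add(stamp(f, config))

      hub <- identify_hubs(gr, config$degree_min, config$betweenness_top_k)
      hubs[[g]] <- hub
      f <- file.path(config$out_dir, paste0("hubs_", g, ".csv"))
      utils::write.csv(hub, f, row.names = FALSE); add(stamp(f, config))
      message("stage networks [", g, "]: ", edge_count(gr), " edges, ",
              sum(hub$hub), " hubs")

      if (all(MOTOR_REGIONS %in% net$regions)) {
        mg <- motor_subnetwork(net, config$tau_motor)
        motor[[g]] <- mg
        f <- file.path(config$out_dir, paste0("motor_", g, ".tsv"))
        write_network(mg, f, "tsv"); add(stamp(f, config))
      }
      if (config$ego_center %in% net$regions) {
        eg <- ego_network(gr, config$ego_center)
        ego[[g]] <- eg
        f <- file.path(config$out_dir, paste0("ego_", g, ".graphml"))
        write_network(eg, f, "graphml"); add(stamp(f, config))
      }
    }
    result$networks <- networks; result$graphs <- graphs
    result$hubs <- hubs; result$motor <- motor; result$ego <- ego

    stage <- "behavior_ml"
    if (config$ml_target %in% names(cohort)) {
      feats <- intersect(config$ml_features, names(cohort))
      ml <- fit_predictors(cohort, features = feats,
                           target = config$ml_target, seed = config$seed)
      f <- file.path(config$out_dir, "ml_metrics.csv")
      utils::write.csv(ml$metrics, f, row.names = FALSE); add(stamp(f, config))
      f <- file.path(config$out_dir, "ml_importance.csv")
      utils::write.csv(ml$importance, f, row.names = FALSE); add(stamp(f, config))
      result$ml <- ml
      message("stage behavior_ml: ", nrow(ml$metrics), " models fitted")
    }
    TRUE
  }, error = function(e) {
    manifest <- write_manifest(config, files, incomplete = stage,
                               error = conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  result$manifest <- write_manifest(config, files)
  invisible(result)
}

write_manifest <- function(config, files, incomplete = NULL, error = NULL) {
  manifest <- list(
    seed = config$seed,
    config = config_hash(config),
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))))
  if (!is.null(incomplete))
    manifest$incomplete <- list(stage = incomplete, error = error)
  jsonlite::write_json(manifest, file.path(config$out_dir, "MANIFEST.json"),
                       auto_unbox = TRUE)
  manifest
}

#' Human-readable summary of a pipeline bundle
#'
#' Reads the bundle directory written by [run_pipeline()] and prints, per
#' group, the whole-brain edge count, the hub list, the motor-subnetwork
#' edge count, and — when present — the model ranking and top features.
#' Every number is read back from the bundle files, never recomputed.
#'
#' @param bundle_dir directory written by [run_pipeline()].
#' @return The report lines, invisibly; they are also printed.
#' @export
summary_report <- function(bundle_dir) {
  manifest_path <- file.path(bundle_dir, "MANIFEST.json")
  if (!file.exists(manifest_path))
    stop("missing bundle component: MANIFEST.json (is '", bundle_dir,
         "' a pipeline bundle?)")
  manifest <- jsonlite::read_json(manifest_path)
  if (!length(manifest$files)) stop("missing bundle component: no files listed")
  lines <- c(paste0("fosnet pipeline bundle: ", bundle_dir),
             paste0("seed ", manifest$seed, ", config ", manifest$config))
  hub_files <- sort(grep("^hubs_.*\\.csv$", names(manifest$files), value = TRUE))
  for (hf in hub_files) {
    g <- sub("^hubs_(.*)\\.csv$", "\\1", hf)
    hubs <- utils::read.csv(file.path(bundle_dir, hf))
    net <- read_network(file.path(bundle_dir, paste0("network_", g, ".graphml")))
    lines <- c(lines, paste0(
      "group ", g, ": ", igraph::ecount(net), " supra-threshold edges; ",
      sum(hubs$hub), " hubs",
      if (sum(hubs$hub)) paste0(" (", paste(hubs$region[hubs$hub],
                                            collapse = ", "), ")") else ""))
    mf <- file.path(bundle_dir, paste0("motor_", g, ".tsv"))
    if (file.exists(mf)) {
      mg <- read_network(mf, "tsv")
      lines <- c(lines, paste0("  motor subnetwork: ", igraph::ecount(mg),
                               " edges over ", igraph::vcount(mg), " regions"))
    }
  }
  mm <- file.path(bundle_dir, "ml_metrics.csv")
  if (file.exists(mm)) {
    metrics <- utils::read.csv(mm)
    ranked <- rank_models(metrics)
    imp <- utils::read.csv(file.path(bundle_dir, "ml_importance.csv"))
    best <- imp[imp$model == ranked$model[1], ]
    best <- best[order(-best$relative), ]
    lines <- c(lines,
               paste0("behavior prediction: best model ", ranked$model[1],
                      " (R2 = ", signif(ranked$r2[1], 3), ", RMSE = ",
                      signif(ranked$rmse[1], 4), ")"),
               paste0("  top features: ",
                      paste(utils::head(best$feature, 3), collapse = ", ")))
  }
  writeLines(lines)
  invisible(lines)
}
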