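# Synthetic cohort generation.
#
# Per-animal regional activity is drawn from a Gaussian copula whose marginals
# are calibrated to a printed summary table: marginal mean = the group mean,
# marginal SD = SEM * sqrt(n) with n taken from the summary. Draws are
# truncated at zero (counts cannot be negative) and the truncated fraction is
# accounted for; a warning fires when it exceeds 1% for any region, which
# happens naturally for regions whose mean sits within ~2 SD of zero.

#' Specify a within-group correlation structure
#'
#' @param group group label the structure applies to.
#' @param regions region abbreviations (order matches `target_r`).
#' @param target_r symmetric correlation matrix with unit diagonal, entries in
#'   \[-1, 1\]; dimnames optional (regions order is used).
#' @return An object of class `correlation_spec`.
#' @export
correlation_spec <- function(group, regions, target_r) {
  target_r <- as.matrix(target_r)
  stopifnot(length(regions) == nrow(target_r), nrow(target_r) == ncol(target_r))
  if (max(abs(target_r - t(target_r))) > 1e-12)
    stop("target_r must be symmetric")
  if (max(abs(diag(target_r) - 1)) > 1e-12)
    stop("target_r must have unit diagonal")
  if (any(abs(target_r) > 1 + 1e-12))
    stop("target_r entries must lie in [-1, 1]")
  dimnames(target_r) <- list(regions, regions)
  structure(list(group = group, regions = regions, target_r = target_r),
            class = "correlation_spec")
}

#' Repair a correlation matrix to the nearest positive-semidefinite one
#'
#' Eigenvalue clipping at zero followed by rescaling to unit diagonal. Matrices
#' whose smallest eigenvalue is below `-1e-4` are treated as specification
#' errors rather than numerical noise and rejected.
#'
#' @param R symmetric matrix with unit diagonal.
#' @return A positive-semidefinite correlation matrix (minimum eigenvalue
#'   >= -1e-8 up to floating point).
#' @export
nearest_psd <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < -1e-4)
    stop("correlation matrix is not repairable (minimum eigenvalue ",
         format(min(e$values), digits = 4), " < -1e-4)")
  if (min(e$values) >= 0) return(R)
  vals <- pmax(e$values, 0)
  M <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(M))
  M <- M / tcrossprod(d)
  diag(M) <- 1
  dimnames(M) <- dimnames(R)
  (M + t(M)) / 2
}

# lower Cholesky-like factor for a PSD correlation matrix (eigendecomposition
# keeps rank-deficient planted structures, e.g. r close to 1, usable)
psd_factor <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(R))
}

#' Generate a per-animal cohort calibrated to a summary table
#'
#' For each group, draws `n_per_group` animals from a Gaussian copula with
#' marginal mean equal to the summary mean and marginal SD equal to
#' `SEM * sqrt(n)` (n from the summary table). Pairs not covered by a
#' [correlation_spec()] are uncorrelated. Negative draws are truncated to
#' zero; the per-region truncated fraction is attached as the
#' `"truncation"` attribute and a warning is raised when it exceeds 1%.
#'
#' @param summary a [group_summary()] providing the marginals.
#' @param n_per_group animals to simulate per group (>= 2).
#' @param corr_specs list of [correlation_spec()] objects (at most one per
#'   group).
#' @param seed integer seed; fixed seed + spec gives identical cohorts.
#' @param groups subset of summary groups to generate (default: all).
#' @return A `cohort_matrix` data.frame with `animal_id`, `group` and one
#'   column per region.
#' @export
generate_cohort <- function(summary, n_per_group, corr_specs = list(),
                            seed = 1, groups = NULL) {
  stopifnot(inherits(summary, "group_summary"), n_per_group >= 2)
  if (inherits(corr_specs, "correlation_spec")) corr_specs <- list(corr_specs)
  if (is.null(groups)) groups <- summary$groups
  stopifnot(all(groups %in% summary$groups))
  regions <- summary$regions$region
  spec_by_group <- list()
  for (cs in corr_specs) {
    stopifnot(inherits(cs, "correlation_spec"))
    if (!cs$group %in% summary$groups)
      stop("correlation spec group '", cs$group, "' not in summary")
    missing <- setdiff(cs$regions, regions)
    if (length(missing))
      stop("correlation spec region(s) not in summary: ",
           paste(missing, collapse = ", "))
    spec_by_group[[cs$group]] <- cs
  }
  p <- length(regions)
  out <- vector("list", length(groups))
  trunc_frac <- matrix(0, p, length(groups), dimnames = list(regions, groups))
  set.seed(seed)
  # one substream per group, derived up front so group subsetting keeps the
  # remaining groups' draws unchanged
  group_seeds <- sapply(summary$groups, function(g)
    sample.int(.Machine$integer.max - 1L, 1))
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    R <- diag(p); dimnames(R) <- list(regions, regions)
    cs <- spec_by_group[[g]]
    if (!is.null(cs)) {
      Rsub <- nearest_psd(cs$target_r)
      R[cs$regions, cs$regions] <- Rsub
    }
    set.seed(group_seeds[[g]])
    Z <- matrix(stats::rnorm(n_per_group * p), n_per_group, p) %*% t(psd_factor(R))
    mu <- summary$mean[, g]
    sdv <- summary$sem[, g] * sqrt(summary$n[[g]])
    X <- sweep(sweep(Z, 2, sdv, `*`), 2, mu, `+`)
    trunc_frac[, gi] <- colMeans(X < 0)
    X[X < 0] <- 0
    colnames(X) <- regions
    out[[gi]] <- data.frame(
      animal_id = sprintf("%s_%03d", g, seq_len(n_per_group)),
      group = g, X, check.names = FALSE, stringsAsFactors = FALSE)
  }
  cohort <- do.call(rbind, out)
  rownames(cohort) <- NULL
  class(cohort) <- c("cohort_matrix", "data.frame")
  attr(cohort, "truncation") <- trunc_frac
  heavy <- which(trunc_frac > 0.01, arr.ind = TRUE)
  if (nrow(heavy))
    warning("truncation at zero exceeded 1% for: ",
            paste(sprintf("%s/%s (%.1f%%)", rownames(trunc_frac)[heavy[, 1]],
                          colnames(trunc_frac)[heavy[, 2]],
                          100 * trunc_frac[heavy]), collapse = ", "))
  cohort
}

#' Specify a behavior/TH column driven by regional activity
#'
#' @param target_column one of `rotarod_s`, `cylinder_rearings`, `th_st`,
#'   `th_sn`.
#' @param driver_regions named numeric vector of weights, names = region
#'   abbreviations; at least one driver.
#' @param noise_sd Gaussian noise SD in target units.
#' @param target_mean centre of the generated column.
#' @param clip_range length-2 numeric; output is clipped into it. Defaults to
#'   `c(0, 480)` for `rotarod_s` (the rotarod assay stops at 480 s) and
#'   `c(0, Inf)` otherwise.
#' @return An object of class `behavior_link_spec`.
#' @export
behavior_link_spec <- function(target_column, driver_regions, noise_sd = 0,
                               target_mean = 0, clip_range = NULL) {
  stopifnot(target_column %in% BEHAVIOR_COLUMNS,
            length(driver_regions) >= 1, !is.null(names(driver_regions)),
            noise_sd >= 0)
  if (is.null(clip_range))
    clip_range <- if (target_column == "rotarod_s") c(0, ROTAROD_MAX_S) else c(0, Inf)
  stopifnot(length(clip_range) == 2, clip_range[1] <= clip_range[2])
  structure(list(target_column = target_column,
                 driver_regions = driver_regions,
                 noise_sd = noise_sd, target_mean = target_mean,
                 clip_range = clip_range),
            class = "behavior_link_spec")
}

#' Add a linked behavior/TH column to a cohort
#'
#' The target is an affine combination of the (centred) driver activities plus
#' Gaussian noise, clipped to the spec's range. With zero noise and a single
#' driver the pre-clipping correlation with the driver is exactly +/-1.
#'
#' @param cohort a cohort data.frame.
#' @param link a [behavior_link_spec()].
#' @param seed integer seed for the noise draws.
#' @param overwrite allow replacing an existing target column.
#' @return The cohort with the target column added.
#' @export
generate_behavior <- function(cohort, link, seed = 1, overwrite = FALSE) {
  stopifnot(inherits(link, "behavior_link_spec"))
  drivers <- names(link$driver_regions)
  missing <- setdiff(drivers, names(cohort))
  if (length(missing))
    stop("driver region(s) absent from cohort: ", paste(missing, collapse = ", "))
  if (link$target_column %in% names(cohort) && !overwrite)
    stop("column '", link$target_column,
         "' already present (set overwrite = TRUE to replace)")
  X <- as.matrix(cohort[drivers])
  signal <- as.vector(scale(X, center = TRUE, scale = FALSE) %*%
                        link$driver_regions)
  set.seed(seed)
  y <- link$target_mean + signal + stats::rnorm(nrow(cohort), 0, link$noise_sd)
  y <- pmin(pmax(y, link$clip_range[1]), link$clip_range[2])
  cohort[[link$target_column]] <- y
  cohort
}

#' Noise SD giving a requested driver-target correlation
#'
#' For a single-driver linear link, `r = sd_signal / sqrt(sd_signal^2 +
#' sd_noise^2)`, so the noise SD achieving a target correlation `r` is
#' `sd_signal * sqrt(1/r^2 - 1)`.
#'
#' @param cohort cohort the link will be applied to.
#' @param driver_regions named weight vector as in [behavior_link_spec()].
#' @param target_r desired absolute Pearson correlation (0 < r <= 1) between
#'   target and the combined driver signal.
#' @return Noise SD in target units.
#' @export
calibrate_noise_sd <- function(cohort, driver_regions, target_r) {
  stopifnot(target_r > 0, target_r <= 1)
  X <- as.matrix(cohort[names(driver_regions)])
  sd_signal <- stats::sd(as.vector(X %*% driver_regions))
  sd_signal * sqrt(1 / target_r^2 - 1)
}

# ---- planted recovery scenarios -------------------------------------------

scenario_matrix <- function(pairs, regions = MOTOR_REGIONS) {
  R <- diag(length(regions))
  dimnames(R) <- list(regions, regions)
  for (p in pairs) R[p[[1]], p[[2]]] <- R[p[[2]], p[[1]]] <- as.numeric(p[[3]])
  R
}

# Planted motor-circuit truth matrices. Supra-threshold pairs sit at
# r >= 0.6 and sub-threshold pairs at r <= 0.35 so that every pair is at
# least 0.1 away from the 0.5 detection threshold; the named edges carry the
# r values reported for the corresponding group's strongest pairs. All three
# matrices are positive definite as written (no repair needed).
SCENARIO_SPECS <- list(
  naive_motor_9edges = list(
    list("DLS", "DMS", 0.986), list("SNr", "M1", 0.783), list("M1", "DMS", 0.742),
    list("M1", "DLS", 0.74), list("SNr", "DLS", 0.70), list("SNr", "DMS", 0.70),
    list("SNpc", "SNr", 0.65), list("SNpc", "DLS", 0.62), list("SNpc", "DMS", 0.62),
    list("M1", "SNpc", 0.30)),
  mptp_motor_3edges = list(
    list("M1", "DLS", 0.727), list("Sm", "SNr", 0.65), list("Sm", "SNpc", 0.65),
    list("SNpc", "SNr", 0.30)),
  acu_motor_7edges = list(
    list("Sm", "DMS", 0.904), list("SNr", "Sm", 0.719), list("SNr", "DMS", 0.719),
    list("SNpc", "SNr", 0.65), list("M1", "SNr", 0.62), list("Gp", "M1", 0.65),
    list("Sm", "DLS", 0.62),
    list("DLS", "DMS", 0.35), list("DLS", "SNr", 0.35), list("M1", "DMS", 0.35),
    list("M1", "Sm", 0.35), list("SNpc", "Sm", 0.35), list("SNpc", "DMS", 0.30),
    list("Gp", "SNr", 0.30), list("M1", "SNpc", 0.20), list("Gp", "DMS", 0.20),
    list("Gp", "Sm", 0.20))
)

SCENARIO_GROUP <- c(naive_motor_9edges = "Naive", mptp_motor_3edges = "MPTP",
                    acu_motor_7edges = "Acu", whole_brain_null = "Naive")

#' Built-in planted-truth recovery scenarios
#'
#' Each scenario pairs the packaged summary marginals with an explicit true
#' within-group correlation matrix. The three motor scenarios plant exactly
#' 9 (Naive-like), 3 (MPTP-like) or 7 (Acu-like) supra-0.5 pairs over the
#' seven motor regions, every pair at least 0.1 away from the 0.5 threshold;
#' `whole_brain_null` has all 435 off-diagonal correlations equal to zero
#' across the full 30-region set.
#'
#' @param name one of `"naive_motor_9edges"`, `"mptp_motor_3edges"`,
#'   `"acu_motor_7edges"`, `"whole_brain_null"`.
#' @return A list with elements `summary` (a [group_summary()] restricted to
#'   the scenario's regions), `corr_specs` (list of [correlation_spec()]),
#'   `group` (the group the structure is planted in) and `truth` (the true
#'   correlation matrix).
#' @export
make_recovery_scenario <- function(name) {
  known <- c(names(SCENARIO_SPECS), "whole_brain_null")
  if (!is.character(name) || length(name) != 1 || !name %in% known)
    stop("unknown scenario '", name, "'; available scenarios: ",
         paste(known, collapse = ", "))
  summary <- fosnet_table1()
  group <- SCENARIO_GROUP[[name]]
  if (name == "whole_brain_null") {
    truth <- diag(nrow(summary$mean))
    dimnames(truth) <- list(summary$regions$region, summary$regions$region)
    return(list(summary = summary, corr_specs = list(), group = group,
                truth = truth))
  }
  truth <- scenario_matrix(SCENARIO_SPECS[[name]])
  summary <- subset_summary(summary, MOTOR_REGIONS)
  list(summary = summary,
       corr_specs = list(correlation_spec(group, MOTOR_REGIONS, truth)),
       group = group, truth = truth)
}
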