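# End-to-end orchestration: simulate -> features -> segments ->
# fit/select -> predict, with a reproducibility manifest.

#' Default candidate covariates of the synthetic scenario
#'
#' A prior selection of 12 covariates (the four static variables plus
#' surface, subsurface and deep-class dynamic climatologies) used as the
#' default candidate pool, keeping the exhaustive 1-4-variable
#' enumeration tractable while covering every depth class and both
#' ground-truth actives of the default scenario.
#'
#' @return Character vector of covariate names.
#' @export
default_candidate_variables <- function() {
  c("Depth", "Slope", "Roughness", "CanArea",
    "mT_surface", "sdGrT_surface", "sdT_0_200", "mT_200_600",
    "mGrT_200_600", "mEKE_200_600", "sdEKE_200_600", "mT_600_2000")
}

stage_time <- function(expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- force(expr)
  list(result = res, seconds = proc.time()[["elapsed"]] - t0)
}

#' Run the full synthetic density-modelling pipeline
#'
#' Executes the five stages in order on a synthetic scenario:
#' (1) simulate bathymetry, canyon areas, monthly dynamic fields and
#' survey effort; (2) derive the candidate covariate set on the common
#' grid; (3) segment the effort into 5-km pieces, filter Beaufort > 4,
#' attach effective-area offsets, extract covariates at midpoints and
#' draw ground-truth Tweedie counts (plus spatial-autocorrelation
#' diagnostics); (4) prune correlated pairs, enumerate and fit all
#' 1-4-variable candidate Tweedie GAMs, compute Akaike weights and
#' summed-weight importance, and fit the final model on the top four
#' mutually uncorrelated variables; (5) predict the relative-density and
#' uncertainty maps from the final model, the 80%-weight ensemble
#' average, and their R^2 comparison. When `out_dir` is given, stage
#' outputs are written (ASCII grids, CSV, GeoJSON, YAML) together with a
#' JSON manifest of per-stage wall-clock times and output checksums.
#'
#' @param config A [scenario_config()].
#' @param out_dir Optional output directory.
#' @param candidate_variables Candidate covariate pool (default
#'   [default_candidate_variables()]).
#' @param max_vars Largest candidate model size (default 4).
#' @param corr_threshold Correlation-pruning threshold (default 0.5).
#' @param cum_weight Ensemble cumulative-weight threshold (default 0.8).
#' @param n_draws Coefficient draws for the uncertainty map.
#' @return An object of class `dd_run` carrying every stage's outputs
#'   (`covariates`, `segments`, `candidates`, `importance`,
#'   `final_variables`, `final_fit`, `metrics`, `autocorr`, `maps`,
#'   `comparison`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         candidate_variables = default_candidate_variables(),
                         max_vars = 4, corr_threshold = 0.5,
                         cum_weight = 0.8, n_draws = 200) {
  stopifnot(inherits(config, "dd_scenario"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("divedsm")),
                   seed = config$seed, stages = list())
  files <- character(0)

  st <- stage_time({
    bathy <- generate_bathymetry(config)
    canyon <- generate_canyon_area(bathy, config)
    stacks <- generate_dynamic_stacks(config, bathy)
    effort <- generate_effort(config)
    list(bathy = bathy, canyon = canyon, stacks = stacks, effort = effort)
  })
  sim <- st$result
  if (!is.null(out_dir)) {
    write_ascii_grid(sim$bathy, file.path(out_dir, "depth.asc"))
    write_ascii_grid(sim$canyon, file.path(out_dir, "canarea.asc"))
    write_tracklines_geojson(sim$effort$tracklines,
                             file.path(out_dir, "tracklines.geojson"))
    write_esw_table(sim$effort$esw_table, file.path(out_dir, "esw.csv"))
    write_scenario_yaml(config, file.path(out_dir, "scenario.yaml"))
    files <- c(files, file.path(out_dir, c("depth.asc", "canarea.asc",
                                           "tracklines.geojson", "esw.csv",
                                           "scenario.yaml")))
  }
  manifest$stages$simulate <- list(seconds = st$seconds)

  st <- stage_time(build_covariate_set(sim$bathy, sim$canyon, sim$stacks))
  covariates <- st$result
  missing_cand <- setdiff(candidate_variables, names(covariates))
  if (length(missing_cand))
    stop("stage features: candidate variable(s) not in covariate set: ",
         paste(missing_cand, collapse = ", "))
  if (!is.null(out_dir)) {
    cov_dir <- file.path(out_dir, "covariates")
    dir.create(cov_dir, showWarnings = FALSE)
    for (nm in candidate_variables) {
      f <- file.path(cov_dir, paste0(nm, ".asc"))
      write_ascii_grid(covariates[[nm]], f)
      files <- c(files, f)
    }
  }
  manifest$stages$features <- list(seconds = st$seconds,
                                   n_covariates = length(covariates))

  st <- stage_time({
    segs <- segment_transects(sim$effort$tracklines, target_length = 5)
    segs <- filter_segments(segs, max_beaufort = 4)
    segs <- attach_offsets(segs, sim$effort$esw_table)
    segs <- extract_covariates(segs, covariates)
    segs <- generate_counts(config$truth, segs,
                            seed = sub_seed(config$seed, "counts"))
    segs
  })
  segments <- st$result
  autoc <- spatial_autocorrelation(segments,
                                   seed = sub_seed(config$seed, "moran"))
  if (!is.null(out_dir)) {
    f <- file.path(out_dir, "segments.csv")
    utils::write.csv(segments, f, row.names = FALSE)
    jsonlite::write_json(
      list(excluded_length_km = attr(segments, "excluded_length_km"),
           log = attr(segments, "log"), autocorrelation = autoc),
      file.path(out_dir, "segments_log.json"), auto_unbox = TRUE,
      digits = NA)
    files <- c(files, f, file.path(out_dir, "segments_log.json"))
  }
  manifest$stages$segments <- list(seconds = st$seconds,
                                   n_segments = nrow(segments))

  # a cubic spline with k = 4 needs more distinct covariate values than
  # knots; near-constant extractions (e.g. canyon area when almost no
  # segment crosses a canyon) are screened out of the candidate pool
  supported <- vapply(candidate_variables, function(v)
    length(unique(segments[[v]])) > 4, TRUE)
  if (any(!supported))
    message("dropping candidate variable(s) with too few distinct values: ",
            paste(candidate_variables[!supported], collapse = ", "))
  candidate_variables <- candidate_variables[supported]
  if (length(candidate_variables) < 2)
    stop("stage fit_select: fewer than 2 usable candidate variables")
  manifest$dropped_variables <- names(supported)[!supported]

  st <- stage_time({
    corr <- correlation_matrix(segments, candidate_variables)
    sets <- enumerate_candidates(candidate_variables, corr,
                                 max_size = max_vars,
                                 threshold = corr_threshold)
    cands <- fit_candidates(segments, sets)
    imp <- variable_importance(cands)
    final_vars <- select_top_uncorrelated(imp, corr, n = 4,
                                          threshold = corr_threshold)
    final_fit <- fit_tweedie_gam(segments, final_vars, p = cands$p)
    list(corr = corr, cands = cands, imp = imp,
         final_vars = final_vars, final_fit = final_fit)
  })
  sel <- st$result
  metrics <- model_metrics(sel$final_fit, segments)
  if (!is.null(out_dir)) {
    utils::write.csv(sel$cands$records,
                     file.path(out_dir, "candidates.csv"), row.names = FALSE)
    imp_out <- sel$imp
    imp_out$importance_pct <- 100 * imp_out$importance
    imp_out$in_final_model <- imp_out$variable %in% sel$final_vars
    utils::write.csv(imp_out, file.path(out_dir, "importance.csv"),
                     row.names = FALSE)
    files <- c(files, file.path(out_dir, c("candidates.csv",
                                           "importance.csv")))
  }
  manifest$stages$fit_select <- list(
    seconds = st$seconds, n_candidates = nrow(sel$cands$records),
    tweedie_p = sel$cands$p,
    final_variables = sel$final_vars)

  st <- stage_time({
    grid <- config$grid
    single <- predict_map(sel$final_fit, covariates, grid)
    unc <- predict_uncertainty(sel$final_fit, covariates, grid,
                               n_draws = n_draws,
                               seed = sub_seed(config$seed, "draws"))
    ens <- ensemble_average(sel$cands, covariates, grid,
                            cum_threshold = cum_weight)
    cmp <- compare_r2(ens$density, single$density)
    list(single = single, unc = unc, ens = ens, cmp = cmp)
  })
  pred <- st$result
  if (!is.null(out_dir)) {
    write_ascii_grid(pred$single$density, file.path(out_dir, "density.asc"))
    write_ascii_grid(pred$unc, file.path(out_dir, "uncertainty.asc"))
    write_ascii_grid(pred$ens$density,
                     file.path(out_dir, "ensemble_density.asc"))
    jsonlite::write_json(pred$cmp, file.path(out_dir, "comparison.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, file.path(out_dir, c("density.asc", "uncertainty.asc",
                                           "ensemble_density.asc",
                                           "comparison.json")))
  }
  manifest$stages$predict <- list(seconds = st$seconds,
                                  r2 = pred$cmp$r2,
                                  ensemble_members = length(pred$ens$members))

  if (!is.null(out_dir)) {
    manifest$checksums <- as.list(tools::md5sum(files))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(config = config, simulated = sim, covariates = covariates,
                 segments = segments, autocorr = autoc,
                 correlation = sel$corr, candidates = sel$cands,
                 importance = sel$imp, final_variables = sel$final_vars,
                 final_fit = sel$final_fit, metrics = metrics,
                 maps = pred, comparison = pred$cmp,
                 manifest = manifest, out_dir = out_dir),
            class = "dd_run")
}

#' @export
print.dd_run <- function(x, ...) {
  cat(sprintf(paste0(
    "<dd_run> %d segments, %d candidate models (p = %.2f)\n",
    "  final model: %s\n  D* = %.1f%%, RMSE = %.3f, R2 vs ensemble = %.3f\n"),
    nrow(x$segments), nrow(x$candidates$records), x$candidates$p,
    paste(x$final_variables, collapse = " + "),
    100 * x$metrics$dev_expl, x$metrics$rmse, x$comparison$r2))
  invisible(x)
}

#' Summarise a pipeline run as a markdown report
#'
#' Renders the variable-importance table, the top of the candidate-model
#' ledger, fit metrics, the autocorrelation diagnostics and the
#' single-vs-ensemble comparison from the numbers already computed by the
#' run (no recomputation), and writes per-variable partial-effect curves
#' as CSV next to the report.
#'
#' @param run A [run_pipeline()] result.
#' @param path Markdown output path (default `report.md` in the run's
#'   output directory).
#' @return The report path, invisibly.
#' @export
run_report <- function(run, path = NULL) {
  stopifnot(inherits(run, "dd_run"))
  if (is.null(path)) {
    if (is.null(run$out_dir)) stop("no out_dir on the run; give a path")
    path <- file.path(run$out_dir, "report.md")
  }
  imp <- run$importance
  rec <- run$candidates$records
  rec <- rec[order(rec$aic), ]
  lines <- c(
    "# Habitat-based density modelling run",
    "",
    sprintf("- Segments: %d (excluded effort: %.1f km)",
            nrow(run$segments),
            attr(run$segments, "excluded_length_km") %||% NA),
    sprintf("- Candidate models: %d, Tweedie p = %.2f",
            nrow(rec), run$candidates$p),
    sprintf("- Final model: %s", paste(run$final_variables, collapse = " + ")),
    sprintf("- Explained deviance D* = %.1f%%, RMSE = %.3f",
            100 * run$metrics$dev_expl, run$metrics$rmse),
    sprintf("- Moran's I = %.3f (p = %.3f), Geary's C = %.3f (p = %.3f)",
            run$autocorr$morans_I, run$autocorr$p_moran,
            run$autocorr$gearys_C, run$autocorr$p_geary),
    sprintf("- Single vs ensemble R2 = %.3f over %d cells (%d ensemble members)",
            run$comparison$r2, run$comparison$n_cells,
            length(run$maps$ens$members)),
    "",
    "## Variable importance (summed Akaike weights)",
    "",
    "| variable | importance (%) | in final model |",
    "|---|---|---|",
    sprintf("| %s | %.1f | %s |", imp$variable, 100 * imp$importance,
            ifelse(imp$variable %in% run$final_variables, "yes", "")),
    "",
    "## Top candidate models",
    "",
    "| variables | AIC | dAIC | w | D* (%) |",
    "|---|---|---|---|---|",
    sprintf("| %s | %.1f | %.2f | %.3f | %.1f |",
            utils::head(rec$variables, 20), utils::head(rec$aic, 20),
            utils::head(rec$delta_aic, 20), utils::head(rec$weight, 20),
            100 * utils::head(rec$dev_expl, 20)))
  writeLines(lines, path)
  for (v in run$final_variables) {
    pe <- partial_effect(run$final_fit, v)
    utils::write.csv(pe, file.path(dirname(path),
                                   paste0("partial_", v, ".csv")),
                     row.names = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
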