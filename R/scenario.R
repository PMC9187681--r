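#' Depth classes of the water column
#'
#' The four strata over which dynamic variables are summarised: the sea
#' surface, the epipelagic zone (0-200 m), the central-water layer
#' (200-600 m) and the deep layer (600-2000 m). Suffixes of covariate
#' names (`mT_surface`, `mEKE_200_600`, ...) use these labels.
#'
#' @return Character vector of the four class labels.
#' @export
depth_classes <- function() c("surface", "0_200", "200_600", "600_2000")

# shallow bound (m) of each class: cells whose seafloor is shallower than
# this have no water in the class and are missing-flagged
depth_class_min <- function() c(surface = 0, "0_200" = 0,
                                "200_600" = 200, "600_2000" = 600)

#' Ground-truth density model for synthetic counts
#'
#' Describes the data-generating process for segment counts: a small set
#' of active covariates with smooth effects on the log scale, a baseline
#' log density (individuals per km^2), and a Tweedie observation model
#' (variance = phi * mean^p, 1 < p < 2, i.e. compound Poisson-gamma).
#'
#' @param active_variables Names of 2-4 covariates that truly drive
#'   density; must be among the generated covariates.
#' @param smooth_shapes Named character vector, one of `"sigmoid"`,
#'   `"dome"`, `"linear"`, `"flat"` per active variable; shapes act on the
#'   standardised (z-score) covariate scale.
#' @param amplitudes Named numeric, effect amplitude on the log scale
#'   (default 1 per variable).
#' @param intercept Baseline log density, log(individuals per km^2).
#' @param tweedie_p Tweedie power index, strictly between 1 and 2.
#' @param dispersion Tweedie dispersion phi (> 0).
#' @return An object of class `dd_true_model`.
#' @export
true_model <- function(active_variables = c("mT_surface", "mEKE_200_600"),
                       smooth_shapes = c(mT_surface = "sigmoid",
                                         mEKE_200_600 = "dome"),
                       amplitudes = NULL,
                       intercept = log(0.05),
                       tweedie_p = 1.4,
                       dispersion = 1.5) {
  stopifnot(length(active_variables) >= 1, length(active_variables) <= 4,
            tweedie_p > 1, tweedie_p < 2, dispersion > 0)
  if (is.null(names(smooth_shapes))) names(smooth_shapes) <- active_variables
  if (is.null(amplitudes))
    amplitudes <- stats::setNames(rep(1, length(active_variables)),
                                  active_variables)
  if (!all(active_variables %in% names(smooth_shapes)))
    stop("every active variable needs a smooth shape")
  structure(list(active_variables = active_variables,
                 smooth_shapes = smooth_shapes,
                 amplitudes = amplitudes,
                 intercept = intercept,
                 tweedie_p = tweedie_p,
                 dispersion = dispersion),
            class = "dd_true_model")
}

#' Evaluate a ground-truth smooth shape
#'
#' @param shape One of `"sigmoid"`, `"dome"`, `"linear"`, `"flat"`.
#' @param z Standardised covariate values.
#' @param amplitude Effect amplitude on the log scale.
#' @return Centred smooth values (mean approximately 0 over standard
#'   normal `z`).
#' @export
eval_smooth_shape <- function(shape, z, amplitude = 1) {
  f <- switch(shape,
    sigmoid = stats::plogis(2 * z) - 0.5,
    dome    = exp(-z^2 / 2) - 0.6,
    linear  = 0.35 * z,
    flat    = rep(0, length(z)),
    stop("unknown smooth shape: ", shape))
  amplitude * f
}

#' Synthetic study scenario
#'
#' Bundles everything needed to simulate a survey: the study-area grid
#' (default the Bay of Biscay box, 10 W-0, 43-50 N at 0.083 degrees), the
#' number of months of dynamic fields, the ground-truth density model, and
#' the survey-effort design.
#'
#' @param seed Integer master seed; all generators are bit-reproducible
#'   given the config.
#' @param lon_min,lon_max,lat_min,lat_max,res Study-area extent and grid
#'   resolution in degrees.
#' @param n_months Number of monthly layers of the dynamic fields (>= 2).
#' @param n_canyons Number of incised canyon channels on the slope (0-5).
#' @param grf_length_scale Correlation length (degrees) of the Gaussian
#'   random fields behind the dynamic variables.
#' @param truth A [true_model()].
#' @param effort List: `n_transects`, `total_length_km`, `platform_mix`
#'   (named probabilities for `ship`/`air`), `beaufort_class_probs`
#'   (probabilities of the five Beaufort classes 0-1, 1-2, 2-3, 3-4, 4-7;
#'   default the observed effort mix of large multi-survey datasets),
#'   `strip_fraction` (share of transects run as 300-m strip surveys).
#' @return An object of class `dd_scenario`.
#' @export
scenario_config <- function(seed = 1L,
                            lon_min = -10, lon_max = 0,
                            lat_min = 43, lat_max = 50,
                            res = 0.083,
                            n_months = 24L,
                            n_canyons = 3L,
                            grf_length_scale = 1,
                            truth = true_model(),
                            effort = list()) {
  stopifnot(res > 0, n_months >= 2, n_canyons >= 0, n_canyons <= 5)
  if (lon_max <= lon_min || lat_max <= lat_min) stop("degenerate extent")
  eff <- utils::modifyList(list(
    n_transects = 60L,
    total_length_km = 15000,
    platform_mix = c(ship = 0.5, air = 0.5),
    beaufort_class_probs = c(0.24, 0.27, 0.25, 0.16, 0.08),
    strip_fraction = 0.1), effort)
  structure(list(seed = as.integer(seed),
                 grid = dd_grid(lon_min, lon_max, lat_min, lat_max, res),
                 n_months = as.integer(n_months),
                 n_canyons = as.integer(n_canyons),
                 grf_length_scale = grf_length_scale,
                 depth_classes = depth_classes(),
                 truth = truth,
                 effort = eff),
            class = "dd_scenario")
}

#' Write or read a scenario configuration as YAML
#'
#' @param config A [scenario_config()].
#' @param path YAML file path.
#' @export
write_scenario_yaml <- function(config, path) {
  g <- config$grid
  x <- list(seed = config$seed,
            extent = list(lon_min = g$lon_min,
                          lon_max = g$lon_min + g$ncol * g$res,
                          lat_min = g$lat_max - g$nrow * g$res,
                          lat_max = g$lat_max),
            res = g$res,
            n_months = config$n_months,
            n_canyons = config$n_canyons,
            grf_length_scale = config$grf_length_scale,
            truth = unclass(config$truth),
            effort = config$effort)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  tm <- x$truth
  scenario_config(seed = x$seed,
                  lon_min = x$extent$lon_min, lon_max = x$extent$lon_max,
                  lat_min = x$extent$lat_min, lat_max = x$extent$lat_max,
                  res = x$res, n_months = x$n_months,
                  n_canyons = x$n_canyons,
                  grf_length_scale = x$grf_length_scale,
                  truth = true_model(
                    active_variables = unlist(tm$active_variables),
                    smooth_shapes = unlist(tm$smooth_shapes),
                    amplitudes = unlist(tm$amplitudes),
                    intercept = tm$intercept,
                    tweedie_p = tm$tweedie_p,
                    dispersion = tm$dispersion),
                  effort = lapply(x$effort, function(e)
                    if (is.list(e)) unlist(e) else e))
}
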