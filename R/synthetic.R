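# Synthetic study generator: bathymetry, canyons, dynamic fields, survey
# effort and Tweedie counts with known ground truth. Everything is
# bit-reproducible from the scenario seed.

# deterministic sub-seed per generator stage, kept within 32-bit range
sub_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587)
}

# shelf-break longitude as a function of latitude: the shelf widens
# northward, so the break migrates west with latitude
shelf_break_lon <- function(lat, lat_min = 43, lat_range = 7) {
  -2.5 - (lat - lat_min) / lat_range * 3.5
}

canyon_incision <- function(config) {
  g <- config$grid
  lon <- grid_lons(g); lat <- grid_lats(g)
  lat_min <- g$lat_max - g$nrow * g$res
  lat_range <- g$nrow * g$res
  inc <- matrix(0, g$nrow, g$ncol)
  if (config$n_canyons == 0) return(inc)
  lats_c <- withr::with_seed(sub_seed(config$seed, "canyons"), {
    picked <- numeric(0)
    lo <- lat_min + 0.5; hi <- g$lat_max - 0.5
    while (length(picked) < config$n_canyons) {
      cand <- stats::runif(1, lo, hi)
      if (all(abs(cand - picked) > 0.6)) picked <- c(picked, cand)
    }
    picked
  })
  w <- 0.09  # cross-channel e-folding half-width, degrees
  for (lc in lats_c) {
    lb <- shelf_break_lon(lat, lat_min, lat_range)
    # smooth box over the slope, following the shelf break
    band <- stats::plogis((outer(lb, lon, function(b, l) l - (b - 1.8))) / 0.2) *
            stats::plogis((outer(lb, lon, function(b, l) (b + 0.6) - l)) / 0.2)
    cross <- exp(-((lat - lc) / w)^2)
    inc <- inc + 600 * cross * band
  }
  inc
}

#' Generate synthetic shelf/slope/canyon bathymetry
#'
#' Builds a smooth seafloor for a Biscay-like margin: a shallow shelf
#' (< 200 m) whose width grows northward, a steep slope band, an abyssal
#' plain deeper than 2000 m, a small seeded random-relief component, and
#' `n_canyons` channels incised across the slope. Depth is positive
#' downward in metres. Deterministic given the scenario seed.
#'
#' @param config A [scenario_config()].
#' @return A [dd_raster()] named `"Depth"` (units m), with attribute
#'   `canyon_mask` (logical matrix of incised cells).
#' @export
generate_bathymetry <- function(config) {
  stopifnot(inherits(config, "dd_scenario"))
  g <- config$grid
  lon <- grid_lons(g); lat <- grid_lats(g)
  lat_min <- g$lat_max - g$nrow * g$res
  lat_range <- g$nrow * g$res
  lb <- shelf_break_lon(lat, lat_min, lat_range)
  shelf <- outer(lb, lon, function(b, l) pmax(3, 180 * l / b))
  ramp <- stats::plogis(outer(lb, lon, function(b, l) (b - l)) / 0.35)
  depth <- shelf + (4800 - shelf) * ramp
  relief <- withr::with_seed(sub_seed(config$seed, "relief"),
    sim_grf(g$nrow, g$ncol, length_scale = 0.5 / g$res))
  depth <- depth + 30 * relief * ramp  # relief only off-shelf
  inc <- canyon_incision(config)
  depth <- pmax(depth + inc, 0)
  out <- dd_raster(g, depth, name = "Depth", units = "m")
  attr(out, "canyon_mask") <- inc > 100
  out
}

#' Canyon surface-area raster
#'
#' Per-cell canyon surface (km^2): the spherical cell area where the cell
#' lies in an incised canyon channel, zero elsewhere.
#'
#' @param bathymetry Output of [generate_bathymetry()].
#' @param config The same [scenario_config()] (used to re-derive the
#'   canyon mask if the bathymetry raster does not carry it).
#' @return A [dd_raster()] named `"CanArea"` (units km^2).
#' @export
generate_canyon_area <- function(bathymetry, config) {
  mask <- attr(bathymetry, "canyon_mask")
  if (is.null(mask)) mask <- canyon_incision(config) > 100
  area <- cell_area_km2(bathymetry$grid)
  area[!mask] <- 0
  dd_raster(bathymetry$grid, area, name = "CanArea", units = "km2")
}

#' Generate monthly dynamic fields per depth class
#'
#' For each depth class and each of temperature (`T`, deg C) and current
#' components (`U`, `V`, m/s), builds `n_months` monthly layers as a
#' deterministic depth-class baseline (cooler and quieter with depth), a
#' seasonal cycle peaking in late summer, and an independent spatially
#' autocorrelated Gaussian random field per month (squared-exponential
#' covariance, length scale `config$grf_length_scale` degrees). Cells of
#' the deeper classes whose seafloor is shallower than the top of the
#' class hold no water there and are missing-flagged.
#'
#' @param config A [scenario_config()].
#' @param bathymetry Optional [generate_bathymetry()] output; regenerated
#'   from `config` if omitted.
#' @return Nested list `stacks[[depth_class]][[variable]]` of
#'   [dd_stack()] objects, variables `T`, `U`, `V`.
#' @export
generate_dynamic_stacks <- function(config, bathymetry = NULL) {
  stopifnot(inherits(config, "dd_scenario"))
  if (is.null(bathymetry)) bathymetry <- generate_bathymetry(config)
  g <- config$grid
  L <- config$grf_length_scale / g$res
  months <- seq_len(config$n_months)
  season <- cos(2 * pi * (months - 8) / 12)  # peak in August
  base_T   <- c(surface = 15, "0_200" = 13, "200_600" = 11, "600_2000" = 6)
  amp_T    <- c(surface = 3, "0_200" = 2, "200_600" = 0.7, "600_2000" = 0.2)
  sd_T     <- c(surface = 0.8, "0_200" = 0.6, "200_600" = 0.4, "600_2000" = 0.3)
  sd_UV    <- c(surface = 0.06, "0_200" = 0.05, "200_600" = 0.035,
                "600_2000" = 0.02)
  cmin <- depth_class_min()
  out <- list()
  for (dc in config$depth_classes) {
    mask <- bathymetry$values < cmin[[dc]]
    stacks <- list()
    for (var in c("T", "U", "V")) {
      arr <- array(NA_real_, c(g$nrow, g$ncol, config$n_months))
      for (m in months) {
        f <- withr::with_seed(
          sub_seed(config$seed, paste("dyn", dc, var, m)),
          sim_grf(g$nrow, g$ncol, L))
        layer <- if (var == "T") {
          base_T[[dc]] + amp_T[[dc]] * season[m] + sd_T[[dc]] * f
        } else {
          sd_UV[[dc]] * f + 0.01 * season[m]
        }
        layer[mask] <- NA_real_
        arr[, , m] <- layer
      }
      stacks[[var]] <- dd_stack(g, arr, name = paste0(var, "_", dc),
                                units = if (var == "T") "degC" else "m s-1")
    }
    out[[dc]] <- stacks
  }
  out
}

#' Vertically average level fields into a depth class
#'
#' Helper for ocean-model output delivered on discrete depth levels rather
#' than pre-averaged classes: thickness-weighted mean of the level rasters
#' whose depth falls inside `[d1, d2]`.
#'
#' @param levels List of [dd_raster()]s, one per model level.
#' @param depths Numeric vector of level depths (m), same length.
#' @param d1,d2 Class bounds (m), `d1 < d2`.
#' @return A [dd_raster()] with the class average.
#' @export
vertical_average <- function(levels, depths, d1, d2) {
  stopifnot(length(levels) == length(depths), d1 < d2)
  keep <- which(depths >= d1 & depths <= d2)
  if (length(keep) == 0) stop("no levels inside the depth class")
  # thickness of the slab each level represents (midpoint rule)
  bounds <- c(d1, (depths[keep][-1] + depths[keep][-length(keep)]) / 2, d2)
  w <- diff(bounds)
  acc <- 0
  for (i in seq_along(keep)) acc <- acc + w[i] * levels[[keep[i]]]$values
  dd_raster(levels[[keep[1]]]$grid, acc / sum(w),
            name = levels[[keep[1]]]$name, units = levels[[keep[1]]]$units)
}

beaufort_class_bounds <- function() {
  list(c(0, 1), c(1, 2), c(2, 3), c(3, 4), c(4, 7))
}

#' Beaufort sea-state class label
#'
#' Classes mirror the standard effort breakdown: `[0,1)`, `[1,2)`,
#' `[2,3)`, `[3,4)`, `[4,7]`.
#'
#' @param beaufort Numeric Beaufort values, 0-7.
#' @return Character labels `"0-1"` ... `"4-7"`.
#' @export
beaufort_class <- function(beaufort) {
  stopifnot(all(beaufort >= 0 & beaufort <= 7))
  labs <- c("0-1", "1-2", "2-3", "3-4", "4-7")
  idx <- pmin(findInterval(beaufort, c(0, 1, 2, 3, 4)), 5L)
  labs[idx]
}

#' Generate synthetic survey effort
#'
#' Lays parallel east-west transects across the study area at jittered
#' evenly spaced latitudes, each of length `total_length_km / n_transects`,
#' and tags every trackline with platform (ship/air), a Beaufort sea state
#' drawn from the configured class mix, an observation-height class and a
#' survey type (line transect, or 300-m strip for a configurable share of
#' ship surveys). Also builds the effective-strip-width (ESW) lookup table
#' per (platform, Beaufort class, height class); ESWs shrink with sea
#' state and are bounded in (0, 2] km.
#'
#' @param config A [scenario_config()].
#' @return List with `tracklines` (class `dd_tracklines`: `attrs` data
#'   frame + `coords` list of lon/lat matrices) and `esw_table` (data
#'   frame: `platform`, `beaufort_class`, `height_class`, `esw_km`).
#' @export
generate_effort <- function(config) {
  stopifnot(inherits(config, "dd_scenario"))
  g <- config$grid
  eff <- config$effort
  n <- eff$n_transects
  len_km <- eff$total_length_km / n
  lat_lo <- g$lat_max - g$nrow * g$res
  withr::with_seed(sub_seed(config$seed, "effort"), {
    lats <- seq(lat_lo + 0.3, g$lat_max - 0.3, length.out = n) +
      stats::runif(n, -0.04, 0.04)
    half_deg <- (len_km / 2) / (111.32 * cos(lats * pi / 180))
    lon_c <- stats::runif(n, g$lon_min + 0.2 + half_deg,
                          g$lon_min + g$ncol * g$res - 0.2 - half_deg)
    survey_type <- ifelse(stats::runif(n) < eff$strip_fraction, "strip", "line")
    platform <- ifelse(survey_type == "strip", "ship",
                       sample(names(eff$platform_mix), n, replace = TRUE,
                              prob = eff$platform_mix))
    bcls <- sample.int(5L, n, replace = TRUE, prob = eff$beaufort_class_probs)
    bounds <- beaufort_class_bounds()
    beaufort <- vapply(bcls, function(ci)
      stats::runif(1, bounds[[ci]][1], bounds[[ci]][2] - 1e-6), 0)
    height_class <- sample(c("low", "high"), n, replace = TRUE)
    coords <- lapply(seq_len(n), function(i) {
      m <- cbind(lon = c(lon_c[i] - half_deg[i], lon_c[i] + half_deg[i]),
                 lat = c(lats[i], lats[i]))
      m
    })
    attrs <- data.frame(id = seq_len(n), platform = platform,
                        survey_type = survey_type, beaufort = beaufort,
                        height_class = height_class,
                        survey = paste0("SYN", ((seq_len(n) - 1) %% 4) + 1),
                        stringsAsFactors = FALSE)
    tracklines <- structure(list(attrs = attrs, coords = coords),
                            class = "dd_tracklines")
    base_esw <- c(ship.high = 1.4, ship.low = 1.1, air.high = 0.9,
                  air.low = 0.7)
    tab <- expand.grid(platform = c("ship", "air"),
                       beaufort_class = c("0-1", "1-2", "2-3", "3-4", "4-7"),
                       height_class = c("low", "high"),
                       stringsAsFactors = FALSE)
    ci <- match(tab$beaufort_class, c("0-1", "1-2", "2-3", "3-4", "4-7"))
    tab$esw_km <- base_esw[paste(tab$platform, tab$height_class, sep = ".")] *
      (1 - 0.12 * (ci - 1))
    rownames(tab) <- NULL
    list(tracklines = tracklines, esw_table = tab)
  })
}

#' Draw Tweedie random deviates (compound Poisson-gamma)
#'
#' Exact sampler for the Tweedie family with power index `1 < p < 2`: a
#' Poisson number `N` of gamma jumps, so `y = 0` with positive
#' probability and `Var(y) = phi * mu^p`.
#'
#' @param n Number of draws.
#' @param mu Mean(s), recycled to length `n`; zero means give zero draws.
#' @param p Power index in (1, 2).
#' @param phi Dispersion (> 0).
#' @return Numeric vector of non-negative draws.
#' @export
rtweedie_cpg <- function(n, mu, p, phi) {
  stopifnot(p > 1, p < 2, phi > 0, all(mu >= 0))
  mu <- rep_len(mu, n)
  y <- numeric(n)
  pos <- mu > 0
  if (any(pos)) {
    lambda <- mu[pos]^(2 - p) / (phi * (2 - p))
    alpha <- (2 - p) / (p - 1)
    scale <- phi * (p - 1) * mu[pos]^(p - 1)
    N <- stats::rpois(sum(pos), lambda)
    yp <- numeric(sum(pos))
    nz <- N > 0
    if (any(nz))
      yp[nz] <- stats::rgamma(sum(nz), shape = N[nz] * alpha,
                              scale = scale[nz])
    y[pos] <- yp
  }
  y
}

#' Generate segment counts from the ground-truth model
#'
#' Segment mean is `mu = effective_area * exp(intercept + sum_j f_j(z_j))`
#' with the active-covariate smooths evaluated on the standardised
#' (z-score over segments) covariate scale; counts are Tweedie draws
#' (compound Poisson-gamma) converted to integers by stochastic rounding
#' (`floor(y) + Bernoulli(frac(y))`), which preserves the mean exactly
#' while matching the integer nature of individual counts.
#'
#' @param truth A [true_model()].
#' @param segments Data frame with `effective_area` and one column per
#'   active covariate (and optionally `id`).
#' @param seed Integer seed.
#' @return `segments` with an integer `count` column appended.
#' @export
generate_counts <- function(truth, segments, seed) {
  stopifnot(inherits(truth, "dd_true_model"))
  if (!"effective_area" %in% names(segments))
    stop("segments must carry effective_area")
  for (v in truth$active_variables) {
    if (!v %in% names(segments))
      stop("missing covariate '", v, "' on segments")
    bad <- which(is.na(segments[[v]]))
    if (length(bad))
      stop("missing covariate '", v, "' on segment(s) ",
           paste(utils::head(if ("id" %in% names(segments))
             segments$id[bad] else bad, 5), collapse = ", "))
  }
  eta <- rep(truth$intercept, nrow(segments))
  for (v in truth$active_variables) {
    x <- segments[[v]]
    z <- (x - mean(x)) / stats::sd(x)
    eta <- eta + eval_smooth_shape(truth$smooth_shapes[[v]], z,
                                   truth$amplitudes[[v]])
  }
  mu <- segments$effective_area * exp(eta)
  withr::with_seed(as.integer(seed), {
    y <- rtweedie_cpg(length(mu), mu, truth$tweedie_p, truth$dispersion)
    fl <- floor(y)
    segments$count <- as.integer(fl + stats::rbinom(length(y), 1L, y - fl))
  })
  segments
}
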