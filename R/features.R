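# Terrain and water-column covariate derivation: neighborhood operators,
# EKE, climatologies and grid resampling.

check_min_size <- function(raster, op) {
  if (all(is.na(raster$values))) stop(op, ": all-missing raster")
  if (nrow(raster$values) < 3 || ncol(raster$values) < 3)
    stop(op, ": raster must be at least 3x3")
}

#' Seafloor slope from a depth raster
#'
#' Per-cell inclination of the seafloor in degrees:
#' `atan(sqrt((dz/dx)^2 + (dz/dy)^2))` with central differences of depth
#' over the metric cell size. The east-west cell size shrinks with
#' latitude (1 degree of longitude = 111.32 cos(lat) km), so the gradient
#' is latitude-corrected row by row. Border cells use one-sided
#' differences; a missing neighbour falls back to the one-sided
#' difference on the valid side, and a cell with no valid neighbour in a
#' direction gets a zero gradient in that direction.
#'
#' @param depth A [dd_raster()] of depth (m, positive down).
#' @return A [dd_raster()] named `"Slope"` (degrees).
#' @export
compute_slope <- function(depth) {
  check_min_size(depth, "compute_slope")
  z <- depth$values
  nr <- nrow(z); nc <- ncol(z)
  lat <- grid_lats(depth$grid)
  dx_m <- depth$grid$res * 111320 * cos(lat * pi / 180)  # per row
  dy_m <- depth$grid$res * 111320
  gx <- matrix(NA_real_, nr, nc); gy <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (is.na(z[i, j])) next
      w <- if (j > 1) z[i, j - 1] else NA
      e <- if (j < nc) z[i, j + 1] else NA
      gx[i, j] <- if (!is.na(w) && !is.na(e)) (e - w) / (2 * dx_m[i])
      else if (!is.na(e)) (e - z[i, j]) / dx_m[i]
      else if (!is.na(w)) (z[i, j] - w) / dx_m[i]
      else 0
      n <- if (i > 1) z[i - 1, j] else NA
      s <- if (i < nr) z[i + 1, j] else NA
      gy[i, j] <- if (!is.na(n) && !is.na(s)) (s - n) / (2 * dy_m)
      else if (!is.na(s)) (s - z[i, j]) / dy_m
      else if (!is.na(n)) (z[i, j] - n) / dy_m
      else 0
    }
  }
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  dd_raster(depth$grid, slope, name = "Slope", units = "deg")
}

#' Terrain roughness
#'
#' Per-cell difference between the maximum and minimum depth over the 3x3
#' neighbourhood. The window includes the central pixel (which leaves
#' max - min unchanged whenever the centre lies within the neighbour
#' range, and matches the usual terrain-function convention); missing
#' neighbours are ignored.
#'
#' @param depth A [dd_raster()] of depth (m).
#' @return A [dd_raster()] named `"Roughness"` (m).
#' @export
compute_roughness <- function(depth) {
  check_min_size(depth, "compute_roughness")
  z <- depth$values
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      win <- z[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
      win <- win[!is.na(win)]
      if (length(win)) out[i, j] <- max(win) - min(win)
    }
  }
  dd_raster(depth$grid, out, name = "Roughness", units = "m")
}

#' Thermal-front gradient
#'
#' Front-detection operator on a temperature field: per cell, the
#' difference between the maximum and minimum temperature among the eight
#' surrounding pixels (central pixel excluded). Missing neighbours are
#' ignored; a cell with fewer than three valid neighbours is set missing.
#'
#' @param temp A [dd_raster()] of temperature (deg C).
#' @return A [dd_raster()] named `"GrT"` (deg C).
#' @export
compute_temperature_gradient <- function(temp) {
  check_min_size(temp, "compute_temperature_gradient")
  z <- temp$values
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      win <- z[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
      ctr <- z[i, j]
      nb <- win[!is.na(win)]
      # drop one instance of the central value (the centre itself)
      if (!is.na(ctr)) nb <- nb[-match(ctr, nb)]
      if (length(nb) >= 3) out[i, j] <- max(nb) - min(nb)
    }
  }
  dd_raster(temp$grid, out, name = paste0("Gr", temp$name), units = temp$units)
}

#' Eddy kinetic energy
#'
#' `EKE = 0.5 * (U^2 + V^2)` from current components on a common grid;
#' missing where either component is missing. Sign-invariant in both
#' components.
#'
#' @param u,v [dd_raster()]s of eastward/northward current (m/s).
#' @return A [dd_raster()] named `"EKE"` (m^2/s^2).
#' @export
compute_eke <- function(u, v) {
  if (!grids_identical(u$grid, v$grid))
    stop("compute_eke: U and V are on different grids")
  dd_raster(u$grid, 0.5 * (u$values^2 + v$values^2),
            name = "EKE", units = "m2 s-2")
}

#' Climatology of a monthly stack
#'
#' Per-cell mean and standard deviation over the time dimension. The sd
#' uses divisor n (population form): the climatology treats the study
#' period as the whole population of months. Cells missing in more than
#' half of the layers are set missing in both outputs.
#'
#' @param stack A [dd_stack()] with at least two layers.
#' @return List with [dd_raster()]s `mean` and `sd` (names prefixed `m`
#'   and `sd`).
#' @export
compute_climatology <- function(stack) {
  stopifnot(inherits(stack, "dd_stack"))
  nl <- n_layers(stack)
  if (nl < 2) stop("compute_climatology: need at least 2 layers for an sd")
  v <- stack$values
  nval <- apply(!is.na(v), c(1, 2), sum)
  mu <- apply(v, c(1, 2), function(x) mean(x, na.rm = TRUE))
  m2 <- apply(v, c(1, 2), function(x) mean(x^2, na.rm = TRUE))
  sdv <- sqrt(pmax(m2 - mu^2, 0))
  bad <- nl - nval > nl / 2
  mu[bad] <- NA_real_; sdv[bad] <- NA_real_
  list(mean = dd_raster(stack$grid, mu, paste0("m", stack$name), stack$units),
       sd = dd_raster(stack$grid, sdv, paste0("sd", stack$name), stack$units))
}

#' Resample a raster onto a target grid
#'
#' Coarsening aggregates by the area-weighted mean of the source cells
#' whose centres fall inside each target cell (weights are spherical cell
#' areas, so the area-weighted grid mean is conserved for aligned grids);
#' a target cell is missing when more than half of its contributing
#' source cells are missing. Refining interpolates bilinearly between
#' source cell centres (missing when more than half of the four
#' surrounding centres are missing).
#'
#' @param raster A [dd_raster()].
#' @param target A [dd_grid()].
#' @return A [dd_raster()] on `target`.
#' @export
resample_to_grid <- function(raster, target) {
  if (grids_identical(raster$grid, target))
    return(dd_raster(target, raster$values, raster$name, raster$units))
  src <- raster$grid
  if (target$res >= src$res) {
    lon <- grid_lons(src); lat <- grid_lats(src)
    idx <- cell_index(target, rep(lon, each = src$nrow),
                      rep(lat, times = src$ncol))
    inside <- !is.na(idx[, 1])
    if (!any(inside)) stop("resample_to_grid: no overlap with target grid")
    w <- as.vector(cell_area_km2(src))
    val <- as.vector(raster$values)
    # column-major linear index into the target matrix
    key <- (idx[inside, 2] - 1) * target$nrow + idx[inside, 1]
    vi <- val[inside]; wi <- w[inside]
    ok <- !is.na(vi)
    n_tot <- rowsum(rep(1, length(key)), key)
    n_ok <- rowsum(as.numeric(ok), key)
    out <- matrix(NA_real_, target$nrow, target$ncol)
    if (any(ok)) {
      num <- rowsum((wi * vi)[ok], key[ok])
      den <- rowsum(wi[ok], key[ok])
      out[as.integer(rownames(num))] <- num[, 1] / den[, 1]
    }
    # majority-missing target cells stay missing
    low <- n_ok[, 1] <= n_tot[, 1] / 2
    out[as.integer(rownames(n_tot))[low]] <- NA_real_
    return(dd_raster(target, out, raster$name, raster$units))
  }
  # refine: bilinear between source cell centres
  slon <- grid_lons(src); slat <- grid_lats(src)  # slat decreasing
  tlon <- grid_lons(target); tlat <- grid_lats(target)
  if (max(tlon) < min(slon) - src$res || min(tlon) > max(slon) + src$res ||
      max(tlat) < min(slat) - src$res || min(tlat) > max(slat) + src$res)
    stop("resample_to_grid: no overlap with target grid")
  out <- matrix(NA_real_, target$nrow, target$ncol)
  for (i in seq_len(target$nrow)) {
    y <- tlat[i]
    i1 <- findInterval(-y, -slat)           # slat[i1] >= y > slat[i1+1]
    i1 <- min(max(i1, 1L), src$nrow - 1L); i2 <- i1 + 1L
    fy <- (slat[i1] - y) / (slat[i1] - slat[i2])
    fy <- min(max(fy, 0), 1)
    for (j in seq_len(target$ncol)) {
      x <- tlon[j]
      j1 <- findInterval(x, slon)
      j1 <- min(max(j1, 1L), src$ncol - 1L); j2 <- j1 + 1L
      fx <- (x - slon[j1]) / (slon[j2] - slon[j1])
      fx <- min(max(fx, 0), 1)
      vv <- c(src11 = raster$values[i1, j1], src12 = raster$values[i1, j2],
              src21 = raster$values[i2, j1], src22 = raster$values[i2, j2])
      ww <- c((1 - fy) * (1 - fx), (1 - fy) * fx, fy * (1 - fx), fy * fx)
      ok <- !is.na(vv)
      if (sum(ok) >= 2) out[i, j] <- sum(ww[ok] * vv[ok]) / sum(ww[ok])
    }
  }
  dd_raster(target, out, raster$name, raster$units)
}

#' Build the full candidate covariate set
#'
#' Assembles the 28 candidate covariates of the habitat models: 4 static
#' rasters (`Depth`, `Slope`, `Roughness`, `CanArea`) plus mean/sd
#' climatologies of temperature, thermal-front gradient and eddy kinetic
#' energy for each of the four depth classes (`mT_*`, `sdT_*`, `mGrT_*`,
#' `sdGrT_*`, `mEKE_*`, `sdEKE_*`). Derived monthly fields (gradients,
#' EKE) are by default computed per monthly layer and then summarised
#' (`gradient_path = "per_month"`), so that their sd climatologies carry
#' the month-to-month variability; `"of_mean"` instead takes the gradient
#' of the temperature climatology (sd then unavailable for gradients).
#' Missing cells of the deeper classes (shelf areas shallower than the
#' class) are filled from the nearest valid cell so that models can
#' predict over the whole grid; filled cells are flagged in each raster's
#' `filled` attribute.
#'
#' @param bathymetry [generate_bathymetry()]-shaped depth raster.
#' @param canyon_area Canyon-surface raster ([generate_canyon_area()]).
#' @param dynamic_stacks Nested list `[[depth_class]][[var]]` of
#'   [dd_stack()]s with variables `T`, `U`, `V`
#'   ([generate_dynamic_stacks()]).
#' @param target_grid Common analysis grid; all outputs are resampled to
#'   it (default: the bathymetry grid).
#' @param gradient_path `"per_month"` (default) or `"of_mean"`.
#' @return Named list of 28 [dd_raster()]s (24 when
#'   `gradient_path = "of_mean"`, which drops the gradient sd terms).
#' @export
build_covariate_set <- function(bathymetry, canyon_area, dynamic_stacks,
                                target_grid = NULL,
                                gradient_path = c("per_month", "of_mean")) {
  gradient_path <- match.arg(gradient_path)
  if (is.null(bathymetry)) stop("missing required input: bathymetry (Depth)")
  if (is.null(canyon_area)) stop("missing required input: canyon_area (CanArea)")
  if (is.null(target_grid)) target_grid <- bathymetry$grid
  out <- list()
  slope <- compute_slope(bathymetry)
  rough <- compute_roughness(bathymetry)
  out$Depth <- resample_to_grid(bathymetry, target_grid)
  out$Slope <- resample_to_grid(slope, target_grid)
  out$Roughness <- resample_to_grid(rough, target_grid)
  out$CanArea <- resample_to_grid(canyon_area, target_grid)
  out$Depth$name <- "Depth"
  for (dc in names(dynamic_stacks)) {
    st <- dynamic_stacks[[dc]]
    for (v in c("T", "U", "V"))
      if (is.null(st[[v]]))
        stop("missing required input: ", v, " stack for class ", dc)
    g <- st$T$grid
    nm <- n_layers(st$T)
    clim_T <- compute_climatology(st$T)
    out[[paste0("mT_", dc)]] <- clim_T$mean
    out[[paste0("sdT_", dc)]] <- clim_T$sd
    if (gradient_path == "per_month") {
      grt <- array(NA_real_, dim(st$T$values))
      for (m in seq_len(nm))
        grt[, , m] <- compute_temperature_gradient(stack_layer(st$T, m))$values
      clim_G <- compute_climatology(dd_stack(g, grt, "GrT", st$T$units))
      out[[paste0("mGrT_", dc)]] <- clim_G$mean
      out[[paste0("sdGrT_", dc)]] <- clim_G$sd
    } else {
      out[[paste0("mGrT_", dc)]] <-
        compute_temperature_gradient(clim_T$mean)
      out[[paste0("mGrT_", dc)]]$name <- "mGrT"
    }
    eke <- array(NA_real_, dim(st$U$values))
    for (m in seq_len(nm))
      eke[, , m] <- compute_eke(stack_layer(st$U, m),
                                stack_layer(st$V, m))$values
    clim_E <- compute_climatology(dd_stack(g, eke, "EKE", "m2 s-2"))
    out[[paste0("mEKE_", dc)]] <- clim_E$mean
    out[[paste0("sdEKE_", dc)]] <- clim_E$sd
  }
  for (nm_i in names(out)) {
    r <- resample_to_grid(out[[nm_i]], target_grid)
    r$name <- nm_i
    if (any(is.na(r$values))) r <- fill_nearest(r)
    out[[nm_i]] <- r
  }
  out
}
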