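#' Regular longitude-latitude grid
#'
#' Defines a regular lon-lat grid with cell-center registration. Cell
#' `(1, 1)` is the north-west corner; row index increases southward,
#' column index increases eastward. All covariate rasters and prediction
#' maps in the package live on such a grid.
#'
#' @param lon_min,lon_max West and east edges in decimal degrees.
#' @param lat_min,lat_max South and north edges in decimal degrees.
#' @param res Cell size in degrees (same in both directions).
#' @return An object of class `dd_grid` with fields `lon_min`, `lat_max`,
#'   `res`, `nrow`, `ncol`.
#' @examples
#' g <- dd_grid(-10, 0, 43, 50, res = 0.083)
#' dim(g)
#' @export
dd_grid <- function(lon_min, lon_max, lat_min, lat_max, res) {
  stopifnot(is.numeric(res), length(res) == 1L, res > 0)
  if (lon_max <= lon_min || lat_max <= lat_min)
    stop("degenerate extent: lon_max > lon_min and lat_max > lat_min required")
  ncol <- max(1L, floor((lon_max - lon_min) / res + 1e-9))
  nrow <- max(1L, floor((lat_max - lat_min) / res + 1e-9))
  structure(
    list(lon_min = lon_min, lat_max = lat_max, res = res,
         nrow = as.integer(nrow), ncol = as.integer(ncol)),
    class = "dd_grid")
}

#' @export
dim.dd_grid <- function(x) c(x$nrow, x$ncol)

#' @export
print.dd_grid <- function(x, ...) {
  cat(sprintf("<dd_grid> %d x %d cells, res %g deg, lon [%g, %g], lat [%g, %g]\n",
              x$nrow, x$ncol, x$res,
              x$lon_min, x$lon_min + x$ncol * x$res,
              x$lat_max - x$nrow * x$res, x$lat_max))
  invisible(x)
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}

#' Cell-center coordinates
#'
#' @param grid A [dd_grid()].
#' @return `grid_lons`: length-`ncol` vector of cell-center longitudes;
#'   `grid_lats`: length-`nrow` vector of cell-center latitudes (north to
#'   south).
#' @export
grid_lons <- function(grid) grid$lon_min + (seq_len(grid$ncol) - 0.5) * grid$res

#' @rdname grid_lons
#' @export
grid_lats <- function(grid) grid$lat_max - (seq_len(grid$nrow) - 0.5) * grid$res

#' Cell areas in square kilometres
#'
#' Spherical cell area: for a cell spanning latitudes `[phi1, phi2]` and
#' `res` degrees of longitude, area = R^2 * res(rad) * (sin phi2 - sin phi1).
#' Exact (to spherical-Earth accuracy), so aggregation by area-weighted
#' means conserves the area-weighted grid mean.
#'
#' @param grid A [dd_grid()].
#' @return `nrow x ncol` matrix of cell areas (km^2).
#' @export
cell_area_km2 <- function(grid) {
  R <- 6371.0088
  lat_top <- grid$lat_max - (seq_len(grid$nrow) - 1) * grid$res
  lat_bot <- lat_top - grid$res
  band <- R^2 * (grid$res * pi / 180) *
    (sin(lat_top * pi / 180) - sin(lat_bot * pi / 180))
  matrix(band, nrow = grid$nrow, ncol = grid$ncol)
}

#' Locate points on a grid
#'
#' @param grid A [dd_grid()].
#' @param lon,lat Point coordinates (degrees).
#' @return A two-column integer matrix `(row, col)`; `NA` rows for points
#'   outside the grid.
#' @export
cell_index <- function(grid, lon, lat) {
  col <- floor((lon - grid$lon_min) / grid$res) + 1
  row <- floor((grid$lat_max - lat) / grid$res) + 1
  # points exactly on the east/south edge belong to the last cell
  col[lon == grid$lon_min + grid$ncol * grid$res] <- grid$ncol
  row[lat == grid$lat_max - grid$nrow * grid$res] <- grid$nrow
  bad <- col < 1 | col > grid$ncol | row < 1 | row > grid$nrow
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Gridded raster layer
#'
#' A single named, unit-tagged field on a [dd_grid()]. Values are stored as
#' an `nrow x ncol` numeric matrix with `NA` flagging missing cells.
#'
#' @param grid A [dd_grid()].
#' @param values Numeric matrix matching `dim(grid)` (or a scalar,
#'   recycled).
#' @param name Variable identifier, e.g. `"Depth"`.
#' @param units Unit string, e.g. `"m"`; required non-empty for physical
#'   variables.
#' @return An object of class `dd_raster`.
#' @export
dd_raster <- function(grid, values, name = "layer", units = "") {
  stopifnot(inherits(grid, "dd_grid"))
  if (length(values) == 1L) values <- matrix(values, grid$nrow, grid$ncol)
  values <- as.matrix(values)
  if (!all(dim(values) == dim(grid)))
    stop(sprintf("values dim %s does not match grid dim %s",
                 paste(dim(values), collapse = "x"),
                 paste(dim(grid), collapse = "x")))
  storage.mode(values) <- "double"
  structure(list(grid = grid, name = name, units = units, values = values),
            class = "dd_raster")
}

#' @export
print.dd_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<dd_raster> %s [%s], %d x %d, range [%s, %s], %d missing\n",
              x$name, x$units, nrow(v), ncol(v),
              format(suppressWarnings(min(v, na.rm = TRUE))),
              format(suppressWarnings(max(v, na.rm = TRUE))),
              sum(is.na(v))))
  invisible(x)
}

#' @export
as.matrix.dd_raster <- function(x, ...) x$values

#' Monthly raster stack
#'
#' Time series of layers of one variable on one grid (e.g. monthly
#' temperature of a depth class): a 3-D array `nrow x ncol x n_layers`.
#'
#' @param grid A [dd_grid()].
#' @param values 3-D array, third dimension indexing time.
#' @param name,units As in [dd_raster()].
#' @return An object of class `dd_stack`.
#' @export
dd_stack <- function(grid, values, name = "layer", units = "") {
  stopifnot(inherits(grid, "dd_grid"), length(dim(values)) == 3L)
  if (!all(dim(values)[1:2] == dim(grid))) stop("stack dims do not match grid")
  structure(list(grid = grid, name = name, units = units, values = values),
            class = "dd_stack")
}

#' @export
print.dd_stack <- function(x, ...) {
  cat(sprintf("<dd_stack> %s [%s], %d x %d x %d layers\n", x$name, x$units,
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3]))
  invisible(x)
}

stack_layer <- function(stack, i) {
  dd_raster(stack$grid, stack$values[, , i], stack$name, stack$units)
}

n_layers <- function(stack) dim(stack$values)[3]

#' Fill missing cells from the nearest valid cell
#'
#' Replaces every `NA` cell with the value of the nearest valid cell
#' (Euclidean distance on cell-center coordinates, longitude scaled by
#' cos(latitude)). Used to extend deep-depth-class covariates over the
#' continental shelf, where the water column is shallower than the class;
#' filled cells are flagged in the `filled` attribute.
#'
#' @param raster A [dd_raster()].
#' @return The filled raster, with a logical matrix attribute `filled`
#'   marking cells whose value was imputed.
#' @export
fill_nearest <- function(raster) {
  v <- raster$values
  na <- is.na(v)
  if (!any(na)) { attr(raster, "filled") <- na; return(raster) }
  if (all(na)) stop("cannot fill an all-missing raster")
  lon <- grid_lons(raster$grid); lat <- grid_lats(raster$grid)
  valid <- which(!na, arr.ind = TRUE)
  miss <- which(na, arr.ind = TRUE)
  coslat <- cos(mean(lat) * pi / 180)
  vx <- lon[valid[, 2]] * coslat; vy <- lat[valid[, 1]]
  for (i in seq_len(nrow(miss))) {
    px <- lon[miss[i, 2]] * coslat; py <- lat[miss[i, 1]]
    j <- which.min((vx - px)^2 + (vy - py)^2)
    v[miss[i, 1], miss[i, 2]] <- raster$values[valid[j, 1], valid[j, 2]]
  }
  out <- dd_raster(raster$grid, v, raster$name, raster$units)
  attr(out, "filled") <- na
  out
}
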