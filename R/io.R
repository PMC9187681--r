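#' Read and write rasters as ESRI ASCII grids
#'
#' The package's native gridded exchange format is the plain-text ESRI
#' ASCII grid (`.asc`): a six-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of values from
#' north to south. Readable by QGIS/GDAL and trivially diffable.
#'
#' @param raster A [dd_raster()].
#' @param path File path (`.asc`).
#' @param name,units Metadata for the raster constructed by
#'   `read_ascii_grid` (the format itself carries neither).
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns a [dd_raster()].
#' @export
write_ascii_grid <- function(raster, path) {
  g <- raster$grid
  hdr <- c(
    sprintf("ncols %d", g$ncol),
    sprintf("nrows %d", g$nrow),
    sprintf("xllcorner %.10f", g$lon_min),
    sprintf("yllcorner %.10f", g$lat_max - g$nrow * g$res),
    sprintf("cellsize %.10f", g$res),
    "NODATA_value -9999")
  v <- raster$values
  v[is.na(v)] <- -9999
  rows <- apply(v, 1, function(r) paste(formatC(r, format = "g", digits = 15),
                                        collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path, name = "layer", units = "") {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  kv <- stats::setNames(vapply(hdr, `[`, "", 2), tolower(vapply(hdr, `[`, "", 1)))
  ncol <- as.integer(kv[["ncols"]]); nrow <- as.integer(kv[["nrows"]])
  res <- as.numeric(kv[["cellsize"]])
  lon_min <- as.numeric(kv[["xllcorner"]])
  lat_max <- as.numeric(kv[["yllcorner"]]) + nrow * res
  nodata <- as.numeric(kv[["nodata_value"]])
  vals <- t(vapply(lines[-(1:6)],
                   function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]),
                   numeric(ncol), USE.NAMES = FALSE))
  vals[vals == nodata] <- NA_real_
  g <- dd_grid(lon_min, lon_min + ncol * res, lat_max - nrow * res, lat_max, res)
  dd_raster(g, vals, name = name, units = units)
}

#' Write tracklines as GeoJSON
#'
#' One `LineString` feature per trackline; platform, Beaufort sea state,
#' observation-height class and survey type travel as feature properties.
#'
#' @param tracklines A `dd_tracklines` object (see [generate_effort()]).
#' @param path Output `.geojson` path.
#' @export
write_tracklines_geojson <- function(tracklines, path) {
  feats <- lapply(seq_len(nrow(tracklines$attrs)), function(i) {
    a <- tracklines$attrs[i, , drop = FALSE]
    list(
      type = "Feature",
      properties = as.list(a),
      geometry = list(type = "LineString",
                      coordinates = unname(apply(tracklines$coords[[i]], 1,
                                                 as.list, simplify = FALSE))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tracklines_geojson
#' @export
read_tracklines_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  coords <- lapply(fc$features, function(f) {
    m <- do.call(rbind, lapply(f$geometry$coordinates,
                               function(p) c(p[[1]], p[[2]])))
    colnames(m) <- c("lon", "lat"); m
  })
  attrs <- do.call(rbind, lapply(fc$features, function(f)
    as.data.frame(f$properties, stringsAsFactors = FALSE)))
  structure(list(attrs = attrs, coords = coords), class = "dd_tracklines")
}

#' Read and write the effective-strip-width lookup table
#'
#' CSV with columns `platform`, `beaufort_class`, `height_class`, `esw_km`,
#' one row per combination of survey platform, Beaufort sea-state class and
#' observation-height class.
#'
#' @param esw_table Data frame with the four columns above.
#' @param path CSV path.
#' @export
write_esw_table <- function(esw_table, path) {
  utils::write.csv(esw_table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_esw_table
#' @export
read_esw_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
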