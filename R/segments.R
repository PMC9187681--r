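# Survey effort processing: 5-km segmentation, sea-state filtering,
# effective-area offsets, sighting assignment, covariate extraction.

haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000
}

# distance along a polyline at each vertex, km
polyline_cumdist <- function(coords) {
  n <- nrow(coords)
  if (n < 2) return(0)
  c(0, cumsum(haversine_km(coords[-n, 1], coords[-n, 2],
                           coords[-1, 1], coords[-1, 2])))
}

# point at arc-length s along a polyline (linear interpolation within edges)
polyline_point <- function(coords, cum, s) {
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(coords) - 1L)
  f <- if (cum[i + 1] > cum[i]) (s - cum[i]) / (cum[i + 1] - cum[i]) else 0
  coords[i, ] + f * (coords[i + 1, ] - coords[i, ])
}

#' Cut tracklines into ~5-km survey segments
#'
#' Each polyline is cut into consecutive pieces of `target_length` km.
#' The residual piece is merged into the last full segment when it is
#' shorter than half the target (avoiding tiny-offset segments that
#' destabilise the GAM) and kept as its own segment otherwise; a line
#' shorter than the target becomes a single segment. Attributes are
#' inherited from the line; the midpoint is the point at half the
#' segment's arc length. Total segmented length equals total input
#' length exactly.
#'
#' @param tracklines A `dd_tracklines` object (attrs + coords).
#' @param target_length Target segment length, km (default 5).
#' @return Data frame of segments: `id`, `line_id`, `lon`, `lat`
#'   (midpoint), `length_km`, plus inherited attributes. Zero-length
#'   lines are skipped and recorded in the `log` attribute.
#' @export
segment_transects <- function(tracklines, target_length = 5) {
  stopifnot(target_length > 0)
  segs <- list(); log <- character(0)
  for (i in seq_along(tracklines$coords)) {
    coords <- tracklines$coords[[i]]
    cum <- polyline_cumdist(coords)
    L <- cum[length(cum)]
    if (L <= 0) {
      log <- c(log, sprintf("line %d skipped: zero length", i))
      next
    }
    n_full <- floor(L / target_length)
    resid <- L - n_full * target_length
    breaks <- seq(0, n_full * target_length, by = target_length)
    if (resid >= target_length / 2 || n_full == 0) {
      breaks <- c(breaks, L)               # residual kept as its own piece
    } else {
      breaks[length(breaks)] <- L          # residual merged into last
    }
    s0 <- breaks[-length(breaks)]; s1 <- breaks[-1]
    mid <- t(vapply(( s0 + s1) / 2, function(s) polyline_point(coords, cum, s),
                    numeric(2)))
    a <- tracklines$attrs[i, setdiff(names(tracklines$attrs), "id"),
                          drop = FALSE]
    segs[[length(segs) + 1L]] <-
      cbind(data.frame(line_id = i, lon = mid[, 1], lat = mid[, 2],
                       length_km = s1 - s0), a, row.names = NULL)
  }
  if (!length(segs)) stop("no non-degenerate tracklines to segment")
  out <- do.call(rbind, segs)
  out <- cbind(id = seq_len(nrow(out)), out)
  attr(out, "log") <- log
  out
}

#' Filter segments by Beaufort sea state
#'
#' Retains segments with Beaufort sea state less than or equal to
#' `max_beaufort` (default 4, the usual detection-reliability cut for
#' deep-diver surveys) and reports the excluded effort.
#'
#' @param segments Segment data frame with a `beaufort` column.
#' @param max_beaufort Inclusive upper bound.
#' @return Filtered segments; attribute `excluded_length_km` holds the
#'   total dropped effort length.
#' @export
filter_segments <- function(segments, max_beaufort = 4) {
  keep <- segments$beaufort <= max_beaufort
  out <- segments[keep, , drop = FALSE]
  attr(out, "excluded_length_km") <- sum(segments$length_km[!keep])
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Attach effective strip widths and effort offsets
#'
#' Line-transect segments get their ESW from the lookup table keyed by
#' (platform, Beaufort class, observation-height class), and an effective
#' area `length * 2 * ESW` km^2. Strip-transect segments bypass the table:
#' a fixed 300-m half-strip gives `length * 2 * 0.3` km^2.
#'
#' @param segments Segment data frame (`platform`, `beaufort`,
#'   `height_class`, `survey_type`, `length_km`).
#' @param esw_table Data frame `platform`, `beaufort_class`,
#'   `height_class`, `esw_km`.
#' @param strip_half_width_km Half-width of strip surveys, km
#'   (default 0.3).
#' @return Segments with `esw_km` and `effective_area` (km^2) columns.
#' @export
attach_offsets <- function(segments, esw_table, strip_half_width_km = 0.3) {
  bc <- beaufort_class(segments$beaufort)
  key <- paste(segments$platform, bc, segments$height_class)
  tab_key <- paste(esw_table$platform, esw_table$beaufort_class,
                   esw_table$height_class)
  idx <- match(key, tab_key)
  line <- segments$survey_type == "line"
  if (any(line & is.na(idx))) {
    miss <- unique(key[line & is.na(idx)])
    stop("no ESW for combination(s): ", paste(miss, collapse = "; "))
  }
  segments$esw_km <- ifelse(line, esw_table$esw_km[idx], strip_half_width_km)
  segments$effective_area <- segments$length_km * 2 * segments$esw_km
  segments
}

#' Assign sightings to segments
#'
#' Each sighting is assigned to the nearest segment midpoint (haversine),
#' restricted to segments of the same survey when both tables carry a
#' `survey` column; the segment count is the sum of assigned group sizes.
#' A sighting farther than one segment length from every candidate
#' segment is left unassigned with a warning.
#'
#' @param segments Segment data frame (`lon`, `lat`, `length_km`).
#' @param sightings Data frame with `lon`, `lat`, `group_size` and
#'   optionally `survey`.
#' @return Segments with an integer `count` column; attribute
#'   `n_unassigned` counts dropped sightings.
#' @export
attach_counts <- function(segments, sightings) {
  counts <- integer(nrow(segments))
  unassigned <- 0L
  by_survey <- !is.null(sightings$survey) && !is.null(segments$survey)
  if (!is.null(sightings) && nrow(sightings)) {
    for (s in seq_len(nrow(sightings))) {
      cand <- if (by_survey) which(segments$survey == sightings$survey[s])
              else seq_len(nrow(segments))
      if (!length(cand)) { unassigned <- unassigned + 1L; next }
      d <- haversine_km(sightings$lon[s], sightings$lat[s],
                        segments$lon[cand], segments$lat[cand])
      j <- which.min(d)
      if (d[j] > segments$length_km[cand[j]]) {
        warning(sprintf("sighting %d is %.1f km from the nearest segment; unassigned",
                        s, d[j]))
        unassigned <- unassigned + 1L
        next
      }
      counts[cand[j]] <- counts[cand[j]] + as.integer(sightings$group_size[s])
    }
  }
  segments$count <- counts
  attr(segments, "n_unassigned") <- unassigned
  segments
}

#' Extract covariate values at segment midpoints
#'
#' Per segment and covariate raster, the value of the grid cell containing
#' the midpoint; if that cell is missing, the nearest valid cell within a
#' one-cell radius (8 neighbours) is used; segments still missing any
#' covariate, or falling outside the grid, are dropped and logged.
#'
#' @param segments Segment data frame with `lon`, `lat`.
#' @param covariates Named list of [dd_raster()]s on a common grid.
#' @return The model-ready segment table (one column appended per
#'   covariate); attribute `log` lists dropped segments.
#' @export
extract_covariates <- function(segments, covariates) {
  stopifnot(length(covariates) >= 1)
  g <- covariates[[1]]$grid
  for (r in covariates) if (!grids_identical(r$grid, g))
    stop("extract_covariates: covariates are not on a common grid")
  idx <- cell_index(g, segments$lon, segments$lat)
  log <- character(0)
  outside <- is.na(idx[, 1])
  if (any(outside))
    log <- c(log, sprintf("segment %s dropped: midpoint outside grid",
                          segments$id[outside]))
  keep <- !outside
  seg <- segments[keep, , drop = FALSE]
  idx <- idx[keep, , drop = FALSE]
  for (nm in names(covariates)) {
    v <- covariates[[nm]]$values
    val <- v[cbind(idx[, 1], idx[, 2])]
    for (s in which(is.na(val))) {
      ri <- idx[s, 1]; ci <- idx[s, 2]
      rr <- max(1, ri - 1):min(nrow(v), ri + 1)
      cc <- max(1, ci - 1):min(ncol(v), ci + 1)
      win <- expand.grid(r = rr, c = cc)
      win <- win[!(win$r == ri & win$c == ci), ]
      wv <- v[cbind(win$r, win$c)]
      if (any(!is.na(wv))) {
        d2 <- (win$r - ri)^2 + (win$c - ci)^2
        d2[is.na(wv)] <- Inf
        val[s] <- wv[which.min(d2)]
      }
    }
    seg[[nm]] <- val
  }
  miss <- rowSums(is.na(as.matrix(seg[names(covariates)]))) > 0
  if (any(miss))
    log <- c(log, sprintf("segment %s dropped: missing covariate after fill",
                          seg$id[miss]))
  out <- seg[!miss, , drop = FALSE]
  attr(out, "log") <- log
  out
}
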