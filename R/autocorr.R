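# Spatial autocorrelation diagnostics on segment counts.

# row-standardised k-nearest-neighbour weight matrix (haversine distances)
knn_weights <- function(lon, lat, k = 8) {
  n <- length(lon)
  stopifnot(n > k)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- haversine_km(lon[i], lat[i], lon, lat)
    d[i] <- Inf
    nb <- order(d)[seq_len(k)]
    W[i, nb] <- 1 / k
  }
  W
}

moran_i <- function(x, W) {
  z <- x - mean(x)
  n <- length(x)
  (n / sum(W)) * as.numeric(t(z) %*% W %*% z) / sum(z^2)
}

geary_c <- function(x, W) {
  z <- x - mean(x)
  n <- length(x)
  num <- sum(W * outer(x, x, function(a, b) (a - b)^2))
  ((n - 1) / (2 * sum(W))) * num / sum(z^2)
}

#' Spatial autocorrelation of segment counts
#'
#' Moran's I and Geary's C on segment counts with row-standardised
#' k-nearest-neighbour weights, with p-values from a seeded permutation
#' test (counts shuffled over segment locations). Moran's p is one-sided
#' for positive autocorrelation (I large); Geary's p one-sided for C
#' small (C < 1 indicates positive autocorrelation). Used as the
#' pre-modelling check that segment counts are not spatially
#' autocorrelated at the segment scale.
#'
#' @param segments Segment data frame with `lon`, `lat`, `count`
#'   (at least 10 rows).
#' @param k Number of nearest neighbours (default 8).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return List: `morans_I`, `gearys_C`, `p_moran`, `p_geary`,
#'   `constant` (TRUE when counts have zero variance, in which case the
#'   statistics are undefined and returned as `NA`).
#' @export
spatial_autocorrelation <- function(segments, k = 8, n_perm = 999, seed = 1) {
  x <- segments$count
  if (length(x) < 10) stop("need at least 10 segments with counts")
  if (stats::sd(x) == 0)
    return(list(morans_I = NA_real_, gearys_C = NA_real_,
                p_moran = NA_real_, p_geary = NA_real_, constant = TRUE))
  # sparse neighbour representation: row i of nb holds the k nearest
  # segments; row-standardised weights are then 1/k, giving O(n k) work
  # per permutation instead of a dense n x n product
  n <- length(x)
  nb <- t(vapply(seq_len(n), function(i) {
    d <- haversine_km(segments$lon[i], segments$lat[i],
                      segments$lon, segments$lat)
    d[i] <- Inf
    order(d)[seq_len(k)]
  }, integer(k)))
  stat_knn <- function(xp) {
    z <- xp - mean(xp)
    nbm <- matrix(z[nb], n, k)
    I <- sum(z * rowMeans(nbm)) / sum(z^2)
    nbx <- matrix(xp[nb], n, k)
    C <- ((n - 1) / (2 * n)) * sum(rowMeans((xp - nbx)^2)) / sum(z^2)
    c(I, C)
  }
  obs <- stat_knn(x)
  I_obs <- obs[1]; C_obs <- obs[2]
  perm <- withr::with_seed(as.integer(seed), {
    t(replicate(n_perm, stat_knn(sample(x))))
  })
  p_moran <- (1 + sum(perm[, 1] >= I_obs)) / (n_perm + 1)
  p_geary <- (1 + sum(perm[, 2] <= C_obs)) / (n_perm + 1)
  list(morans_I = I_obs, gearys_C = C_obs,
       p_moran = p_moran, p_geary = p_geary, constant = FALSE)
}
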