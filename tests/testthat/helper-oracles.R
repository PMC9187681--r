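# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity with the most literal method available (nested
# loops, power-set scans, closed forms) and never call the package paths
# they check.

oracle_roughness <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    vals <- c()
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && !is.na(z[ii, jj]))
        vals <- c(vals, z[ii, jj])
    }
    if (length(vals)) out[i, j] <- max(vals) - min(vals)
  }
  out
}

oracle_gradient <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    vals <- c()
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && !is.na(z[ii, jj]))
        vals <- c(vals, z[ii, jj])
    }
    if (length(vals) >= 3) out[i, j] <- max(vals) - min(vals)
  }
  out
}

oracle_slope <- function(z, lats, res) {
  nr <- nrow(z); nc <- ncol(z)
  dy <- res * 111320
  out <- matrix(NA_real_, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    dx <- res * 111320 * cos(lats[i] * pi / 180)
    gx <- if (j == 1) (z[i, 2] - z[i, 1]) / dx
          else if (j == nc) (z[i, nc] - z[i, nc - 1]) / dx
          else (z[i, j + 1] - z[i, j - 1]) / (2 * dx)
    gy <- if (i == 1) (z[2, j] - z[1, j]) / dy
          else if (i == nr) (z[nr, j] - z[nr - 1, j]) / dy
          else (z[i + 1, j] - z[i - 1, j]) / (2 * dy)
    out[i, j] <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  }
  out
}

oracle_climatology <- function(arr) {
  nr <- dim(arr)[1]; nc <- dim(arr)[2]
  mu <- matrix(NA_real_, nr, nc); sdv <- matrix(NA_real_, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    x <- arr[i, j, ]
    x <- x[!is.na(x)]
    if (dim(arr)[3] - length(x) <= dim(arr)[3] / 2) {
      mu[i, j] <- mean(x)
      sdv[i, j] <- sqrt(mean((x - mean(x))^2))  # divisor n
    }
  }
  list(mean = mu, sd = sdv)
}

# aggregate a fine matrix by integer factor using area weights
oracle_block_mean <- function(z, fac, areas) {
  nr <- nrow(z) / fac; nc <- ncol(z) / fac
  out <- matrix(NA_real_, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    ri <- ((i - 1) * fac + 1):(i * fac); cj <- ((j - 1) * fac + 1):(j * fac)
    v <- z[ri, cj]; w <- areas[ri, cj]
    out[i, j] <- sum(w * v) / sum(w)
  }
  out
}

# 4-connected component count of a logical matrix (BFS)
oracle_n_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  n <- 0L
  for (i in 1:nr) for (j in 1:nc) {
    if (!mask[i, j] || seen[i, j]) next
    n <- n + 1L
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
            mask[q[1], q[2]] && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  n
}

# textbook Moran's I / Geary's C from the standard double-sum formulas
oracle_moran <- function(x, W) {
  n <- length(x); z <- x - mean(x)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

oracle_geary <- function(x, W) {
  n <- length(x); z <- x - mean(x)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + W[i, j] * (x[i] - x[j])^2
  ((n - 1) / (2 * sum(W))) * num / sum(z^2)
}

# power-set filter for candidate enumeration (bitmask scan)
oracle_enumerate <- function(vars, corr, max_size, threshold) {
  vars <- sort(vars)
  p <- length(vars)
  sets <- list()
  for (mask in 1:(2^p - 1)) {
    s <- vars[bitwAnd(mask, 2^(seq_len(p) - 1)) > 0]
    if (length(s) > max_size) next
    ok <- TRUE
    if (length(s) > 1)
      for (a in 1:(length(s) - 1)) for (b in (a + 1):length(s))
        if (abs(corr[s[a], s[b]]) > threshold) ok <- FALSE
    if (ok) sets[[length(sets) + 1L]] <- s
  }
  # same deterministic order as the package: by size then lexicographic
  key <- vapply(sets, function(s)
    sprintf("%d|%s", length(s), paste(s, collapse = ",")), "")
  sets[order(key)]
}

# simulated segment table with independent standard-normal covariates and
# ground-truth Tweedie counts
sim_segment_table <- function(n, n_covs, seed, truth, area = 10) {
  withr::with_seed(seed, {
    tab <- as.data.frame(matrix(rnorm(n * n_covs), n, n_covs))
    names(tab) <- paste0("x", sprintf("%02d", seq_len(n_covs)))
    tab$id <- seq_len(n)
    tab$effective_area <- rep_len(area, n)
    tab
  })
}

default_test_truth <- function(actives = c("x01", "x02"),
                               shapes = c(x01 = "sigmoid", x02 = "dome"),
                               intercept = log(0.08), p = 1.4, phi = 1.5) {
  true_model(active_variables = actives, smooth_shapes = shapes,
             intercept = intercept, tweedie_p = p, dispersion = phi)
}

# tiny scenario for pipeline tests: coarse grid, few months, fewer transects
small_scenario <- function(seed = 11, ...) {
  scenario_config(seed = seed, res = 0.25, n_months = 4,
                  effort = list(n_transects = 30, total_length_km = 4000),
                  ...)
}
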