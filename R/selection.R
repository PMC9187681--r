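# Multi-model inference: correlation pruning, exhaustive 1-4 variable
# enumeration, Akaike weights, summed-weight importance, top-4
# uncorrelated model, 80%-weight ensemble averaging and the R^2
# single-model approximation check.

#' Pairwise Pearson correlation of covariates over segments
#'
#' @param table Segment table.
#' @param variables Covariate column names (>= 2); the table must have at
#'   least 3 rows.
#' @return Symmetric correlation matrix with unit diagonal. Zero-variance
#'   columns are flagged in the `zero_variance` attribute and given zero
#'   correlation with everything (they carry no signal to collide with).
#' @export
correlation_matrix <- function(table, variables = NULL) {
  if (is.null(variables)) variables <- setdiff(
    names(table)[vapply(table, is.numeric, TRUE)],
    c("id", "line_id", "lon", "lat", "length_km", "beaufort", "esw_km",
      "effective_area", "count"))
  stopifnot(length(variables) >= 2, nrow(table) >= 3)
  X <- as.matrix(table[, variables, drop = FALSE])
  zv <- apply(X, 2, stats::sd) == 0
  C <- suppressWarnings(stats::cor(X))
  C[zv, ] <- 0; C[, zv] <- 0
  diag(C) <- 1
  attr(C, "zero_variance") <- variables[zv]
  C
}

#' Enumerate candidate variable subsets
#'
#' All subsets of 1 to `max_size` variables containing no pair with
#' `|r| > threshold` (strict: a pair at exactly the threshold is
#' allowed), in deterministic order (by size, then lexicographic).
#'
#' @param variables Candidate covariate names.
#' @param corr Correlation matrix covering `variables`.
#' @param max_size Largest subset size (default 4).
#' @param threshold Correlation-pruning threshold (default 0.5).
#' @return List of character vectors.
#' @export
enumerate_candidates <- function(variables, corr, max_size = 4,
                                 threshold = 0.5) {
  if (!length(variables)) stop("empty variable list")
  variables <- sort(variables)
  if (!all(variables %in% rownames(corr)))
    stop("correlation matrix does not cover all variables")
  ok_pair <- abs(corr[variables, variables, drop = FALSE]) <= threshold
  sets <- list()
  for (size in seq_len(min(max_size, length(variables)))) {
    cmb <- utils::combn(variables, size, simplify = FALSE)
    for (s in cmb) {
      if (size == 1 || all(ok_pair[s, s][upper.tri(diag(size))]))
        sets[[length(sets) + 1L]] <- s
    }
  }
  sets
}

#' Akaike weights from AICs
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AIC_i - min(AIC)`; the min-shift makes the computation
#' numerically stable and leaves weights invariant to adding any constant
#' to all AICs.
#'
#' @param aics Numeric vector of AICs (at least one finite).
#' @return Weights summing to 1; infinite AICs get weight 0.
#' @export
akaike_weights <- function(aics) {
  if (!any(is.finite(aics))) stop("all AICs are infinite")
  d <- aics - min(aics[is.finite(aics)])
  w <- ifelse(is.finite(d), exp(-d / 2), 0)
  w / sum(w)
}

#' Fit all candidate models
#'
#' Fits one Tweedie GAM per candidate variable subset and attaches AIC,
#' explained deviance and Akaike weight. The Tweedie power index is
#' profiled once — on the best single-variable model — and then held
#' fixed across all candidates so their AICs are compared under one
#' family; enumeration fits use unpenalised fixed-df smooths
#' (`fixed_df = TRUE`) by default.
#'
#' @param table Model-ready segment table.
#' @param sets List of variable subsets ([enumerate_candidates()]).
#' @param k Basis dimension per smooth.
#' @param p Tweedie power; `NULL` to profile as described.
#' @param fixed_df Passed to [fit_tweedie_gam()] (default TRUE).
#' @return Object of class `dd_candidates`: `records` data frame
#'   (`model_id`, `variables`, `n_vars`, `aic`, `delta_aic`, `dev_expl`,
#'   `weight`), `fits` list of `dd_gam`, and the `p` used.
#' @export
fit_candidates <- function(table, sets, k = 4, p = NULL, fixed_df = TRUE) {
  stopifnot(length(sets) >= 1)
  if (is.null(p)) {
    singles <- unique(unlist(sets))
    aic1 <- vapply(singles, function(v)
      fit_tweedie_gam(table, v, k = k, p = 1.5, fixed_df = TRUE)$aic, 0)
    best_var <- singles[which.min(aic1)]
    p <- fit_tweedie_gam(table, best_var, k = k, p = NULL,
                         fixed_df = TRUE)$p
  }
  fits <- lapply(sets, function(s)
    fit_tweedie_gam(table, s, k = k, p = p, fixed_df = fixed_df))
  rec <- data.frame(
    model_id = seq_along(sets),
    variables = vapply(sets, paste, "", collapse = "+"),
    n_vars = lengths(sets),
    aic = vapply(fits, `[[`, 0, "aic"),
    dev_expl = vapply(fits, `[[`, 0, "dev_expl"),
    stringsAsFactors = FALSE)
  rec$delta_aic <- rec$aic - min(rec$aic)
  rec$weight <- akaike_weights(rec$aic)
  structure(list(records = rec, fits = fits, sets = sets, p = p),
            class = "dd_candidates")
}

#' @export
print.dd_candidates <- function(x, ...) {
  cat(sprintf("<dd_candidates> %d models, p = %.2f, best: %s (w = %.3f)\n",
              nrow(x$records), x$p,
              x$records$variables[which.min(x$records$aic)],
              max(x$records$weight)))
  invisible(x)
}

#' Summed-weight variable importance
#'
#' The importance of a variable is the sum of the Akaike weights of the
#' candidate models in which it appears; variables are ranked by
#' descending importance (ties broken alphabetically).
#'
#' @param candidates A [fit_candidates()] result, or a data frame with
#'   `weight` plus a list of `sets`.
#' @return Data frame `variable`, `importance`, `rank`, sorted by rank.
#' @export
variable_importance <- function(candidates) {
  sets <- candidates$sets
  w <- candidates$records$weight
  vars <- sort(unique(unlist(sets)))
  imp <- vapply(vars, function(v)
    sum(w[vapply(sets, function(s) v %in% s, TRUE)]), 0)
  ord <- order(-imp, vars)
  data.frame(variable = vars[ord], importance = unname(imp[ord]),
             rank = seq_along(vars), stringsAsFactors = FALSE)
}

#' Select the top-n mutually uncorrelated variables
#'
#' Greedy walk down the importance ranking: a variable is added iff its
#' absolute correlation with every already-chosen variable does not
#' exceed the threshold, until `n` variables are chosen or the ranking is
#' exhausted (so a highly ranked variable can be skipped in favour of the
#' next uncorrelated one).
#'
#' @param importance [variable_importance()] output.
#' @param corr Correlation matrix covering the ranked variables.
#' @param n Number of variables to select (default 4).
#' @param threshold Correlation threshold (default 0.5).
#' @return Character vector of selected variables, in selection order.
#' @export
select_top_uncorrelated <- function(importance, corr, n = 4,
                                    threshold = 0.5) {
  chosen <- character(0)
  for (v in importance$variable) {
    if (length(chosen) >= n) break
    if (all(abs(corr[v, chosen]) <= threshold))
      chosen <- c(chosen, v)
  }
  if (!length(chosen)) stop("no selectable variables")
  chosen
}

#' Weighted ensemble-average prediction map
#'
#' Members are the smallest prefix of the weight-sorted candidate models
#' whose cumulative Akaike weight reaches `cum_threshold` (a model
#' straddling the threshold is included); beyond it, models are treated
#' as negligible. The averaged map is the weighted mean of member
#' density maps with weights renormalised within the member set.
#'
#' @param candidates A [fit_candidates()] result.
#' @param covariates Named list of [dd_raster()]s.
#' @param grid Prediction [dd_grid()].
#' @param cum_threshold Cumulative-weight threshold (default 0.8).
#' @return List: `members` (indices into the candidate list, descending
#'   weight), `weights` (renormalised), `density` (averaged
#'   [dd_raster()]), `raw_cum_weight`.
#' @export
ensemble_average <- function(candidates, covariates, grid,
                             cum_threshold = 0.8) {
  rec <- candidates$records
  ord <- order(-rec$weight, rec$variables)
  cum <- cumsum(rec$weight[ord])
  n_keep <- which(cum >= cum_threshold)[1]
  if (is.na(n_keep)) n_keep <- length(ord)
  members <- ord[seq_len(n_keep)]
  w <- rec$weight[members] / sum(rec$weight[members])
  acc <- NULL
  for (i in seq_along(members)) {
    dmap <- predict_map(candidates$fits[[members[i]]], covariates,
                        grid)$density$values
    acc <- if (is.null(acc)) w[i] * dmap else acc + w[i] * dmap
  }
  list(members = members, weights = w,
       raw_cum_weight = cum[n_keep],
       density = dd_raster(grid, acc, name = "ensemble_density",
                           units = "ind per 100 km2"))
}

#' Compare single-model and ensemble-average predictions
#'
#' Ordinary least-squares regression of the single-model map on the
#' averaged map over mutually valid cells; the R^2 of that line measures
#' whether the single model approximates the model average (scale-free:
#' proportional maps give R^2 = 1). Passes at `r2_threshold`
#' (default 0.9, operationalising "close to 1").
#'
#' @param average_map,single_map [dd_raster()]s on identical grids with
#'   at least 30 mutually valid cells.
#' @param r2_threshold Pass threshold.
#' @return List: `r2`, `n_cells`, `pass`, `constant` (TRUE when either
#'   map is constant, leaving R^2 undefined).
#' @export
compare_r2 <- function(average_map, single_map, r2_threshold = 0.9) {
  if (!grids_identical(average_map$grid, single_map$grid))
    stop("maps are on different grids")
  a <- as.vector(average_map$values)
  s <- as.vector(single_map$values)
  ok <- !is.na(a) & !is.na(s)
  if (sum(ok) < 30) stop("fewer than 30 mutually valid cells")
  if (stats::sd(a[ok]) == 0 || stats::sd(s[ok]) == 0)
    return(list(r2 = NA_real_, n_cells = sum(ok), pass = NA,
                constant = TRUE))
  # R^2 of the OLS regression of single on average = squared Pearson r
  r2 <- stats::cor(s[ok], a[ok])^2
  list(r2 = r2, n_cells = sum(ok), pass = r2 >= r2_threshold,
       constant = FALSE)
}
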