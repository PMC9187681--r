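# Tweedie GAM engine: log-link smooth models of segment counts with
# log-effective-area offsets, fitted with mgcv; the density-surface layer
# (maps, uncertainty, metrics) on top.

#' Default profile grid for the Tweedie power index
#' @return Numeric vector 1.1, 1.15, ..., 1.9.
#' @export
tweedie_p_grid <- function() seq(1.1, 1.9, by = 0.05)

gam_formula <- function(variables, k, fixed_df, count_col, offset_col) {
  rhs <- if (length(variables)) {
    paste(sprintf("s(%s, k = %d, bs = \"cr\"%s)", variables, k,
                  if (fixed_df) ", fx = TRUE" else ""), collapse = " + ")
  } else "1"
  stats::as.formula(sprintf("%s ~ %s + offset(log(%s))",
                            count_col, rhs, offset_col))
}

fit_one_gam <- function(table, variables, k, p, fixed_df, count_col,
                        offset_col) {
  fam <- if (p == 1) stats::poisson(link = "log")
         else mgcv::Tweedie(p = p, link = "log")
  form <- gam_formula(variables, k, fixed_df, count_col, offset_col)
  fit <- mgcv::gam(form, family = fam, data = table,
                   method = if (fixed_df) "GCV.Cp" else "REML")
  if (!fit$converged)
    stop("GAM did not converge for variables: ",
         paste(variables, collapse = ", "))
  fit
}

#' Fit a Tweedie GAM of segment counts
#'
#' Counts per segment are modelled as smooth functions of 0-4 covariates
#' on the log scale with an offset of log effective area: cubic
#' regression-spline bases of size `k = 4` per smooth (sum-to-zero
#' constrained, so 3 estimable degrees of freedom per curve), Tweedie
#' family with log link. The power index `p` is either supplied or chosen
#' by profiling the series-evaluated Tweedie log-likelihood over a fixed
#' grid; the dispersion is the Pearson estimate. By default smooths are
#' lightly penalised with REML-chosen smoothing within the fixed basis;
#' `fixed_df = TRUE` fits them unpenalised at exactly the basis
#' dimension, which is what the exhaustive model enumeration uses.
#'
#' @param table Model-ready segment table (counts, offsets, covariates).
#' @param variables Character vector of 0-4 covariate names (empty = null
#'   model).
#' @param k Basis dimension per smooth (default 4).
#' @param p Tweedie power index in (1, 2), `1` for the Poisson limit, or
#'   `NULL` to profile over [tweedie_p_grid()].
#' @param fixed_df Fit smooths unpenalised at the full basis dimension.
#' @param count_col,offset_col Column names of the response and the
#'   effective area.
#' @return An object of class `dd_gam`: the mgcv fit plus `variables`,
#'   `p`, `phi` (Pearson dispersion), `loglik`, `edf`, `aic` (identity
#'   `aic = -2 loglik + 2 edf` exact), `dev_expl`, and the training
#'   covariate ranges used for the extrapolation mask.
#' @export
fit_tweedie_gam <- function(table, variables, k = 4, p = NULL,
                            fixed_df = FALSE, count_col = "count",
                            offset_col = "effective_area") {
  stopifnot(length(variables) <= 4)
  if (!count_col %in% names(table)) stop("missing count column: ", count_col)
  if (!offset_col %in% names(table)) stop("missing offset column: ", offset_col)
  miss <- setdiff(variables, names(table))
  if (length(miss)) stop("missing covariates: ", paste(miss, collapse = ", "))
  if (nrow(table) <= length(variables) * k + 1)
    stop("fewer rows than total basis dimension")
  if (is.null(p)) {
    fits <- lapply(tweedie_p_grid(), function(pp)
      fit_one_gam(table, variables, k, pp, fixed_df, count_col, offset_col))
    lls <- vapply(fits, function(f) as.numeric(stats::logLik(f)), 0)
    best <- which.max(lls)
    fit <- fits[[best]]; p <- tweedie_p_grid()[best]
  } else {
    stopifnot(p == 1 || (p > 1 && p < 2))
    fit <- fit_one_gam(table, variables, k, p, fixed_df, count_col,
                       offset_col)
  }
  ll <- stats::logLik(fit)
  edf <- attr(ll, "df")
  ranges <- lapply(variables, function(v) range(table[[v]]))
  names(ranges) <- variables
  structure(list(
    gam = fit, variables = variables, k = k, p = p,
    phi = fit$scale,
    loglik = as.numeric(ll), edf = edf,
    aic = -2 * as.numeric(ll) + 2 * edf,
    dev_expl = 1 - fit$deviance / fit$null.deviance,
    n = nrow(table),
    count_col = count_col, offset_col = offset_col,
    ranges = ranges), class = "dd_gam")
}

#' @export
print.dd_gam <- function(x, ...) {
  cat(sprintf("<dd_gam> %s | p = %.2f, phi = %.3f, AIC = %.2f, D* = %.1f%%\n",
              if (length(x$variables)) paste(x$variables, collapse = " + ")
              else "(null)", x$p, x$phi, x$aic, 100 * x$dev_expl))
  invisible(x)
}

#' Partial effect of one smooth with pointwise 95% interval
#'
#' Evaluates the centred smooth of one covariate over a grid of its
#' observed range, with approximate pointwise 95% confidence bounds from
#' the coefficient covariance.
#'
#' @param fit A [fit_tweedie_gam()] result.
#' @param variable One of `fit$variables`.
#' @param n Grid length (default 100).
#' @return Data frame `x`, `fit`, `lo95`, `hi95` (log scale, centred).
#' @export
partial_effect <- function(fit, variable, n = 100) {
  stopifnot(inherits(fit, "dd_gam"), variable %in% fit$variables)
  newd <- as.data.frame(lapply(fit$ranges, function(r) rep(mean(r), n)))
  newd[[variable]] <- seq(fit$ranges[[variable]][1],
                          fit$ranges[[variable]][2], length.out = n)
  newd[[fit$offset_col]] <- 1
  pt <- stats::predict(fit$gam, newdata = newd, type = "terms",
                       se.fit = TRUE)
  term <- grep(paste0("s\\(", variable, "\\)"), colnames(pt$fit))
  data.frame(x = newd[[variable]],
             fit = pt$fit[, term],
             lo95 = pt$fit[, term] - 1.96 * pt$se.fit[, term],
             hi95 = pt$fit[, term] + 1.96 * pt$se.fit[, term])
}

#' Fit metrics: explained deviance and RMSE
#'
#' `D* = 1 - deviance(model) / deviance(null)`; RMSE is computed on the
#' response (count) scale: `sqrt(mean((observed - fitted)^2))`.
#'
#' @param fit A [fit_tweedie_gam()] result.
#' @param table The table the model was fitted to.
#' @return List `dev_expl`, `rmse`.
#' @export
model_metrics <- function(fit, table) {
  stopifnot(inherits(fit, "dd_gam"))
  obs <- table[[fit$count_col]]
  pred <- as.numeric(stats::predict(fit$gam, newdata = table,
                                    type = "response"))
  list(dev_expl = fit$dev_expl, rmse = sqrt(mean((obs - pred)^2)))
}

map_newdata <- function(fit, covariates, grid) {
  for (v in fit$variables) {
    if (is.null(covariates[[v]]))
      stop("missing covariate raster: ", v)
    if (!grids_identical(covariates[[v]]$grid, grid))
      stop("covariate ", v, " not on the prediction grid")
  }
  ncell <- grid$nrow * grid$ncol
  cols <- lapply(fit$variables, function(v) as.vector(covariates[[v]]$values))
  names(cols) <- fit$variables
  cols[[fit$offset_col]] <- rep(1, ncell)
  nd <- as.data.frame(cols)
  valid <- if (length(fit$variables))
    rowSums(is.na(nd[, fit$variables, drop = FALSE])) == 0
  else rep(TRUE, nrow(nd))
  extrap <- rep(FALSE, nrow(nd))
  for (v in fit$variables) {
    r <- fit$ranges[[v]]
    extrap <- extrap | (!is.na(nd[[v]]) & (nd[[v]] < r[1] | nd[[v]] > r[2]))
  }
  list(nd = nd, valid = valid, extrap = extrap)
}

#' Predict a relative-density map
#'
#' Evaluates the fitted model over every valid grid cell at unit
#' effective area, giving expected individuals per km^2, and rescales to
#' individuals per 100 km^2. Cells where any covariate lies outside its
#' observed training range are flagged in the extrapolation mask.
#'
#' @param fit A [fit_tweedie_gam()] result.
#' @param covariates Named list of [dd_raster()]s covering
#'   `fit$variables`.
#' @param grid Prediction [dd_grid()].
#' @return List: `density` ([dd_raster()], individuals per 100 km^2) and
#'   `extrapolated` (logical-valued [dd_raster()]).
#' @export
predict_map <- function(fit, covariates, grid) {
  md <- map_newdata(fit, covariates, grid)
  dens <- rep(NA_real_, nrow(md$nd))
  dens[md$valid] <- as.numeric(stats::predict(
    fit$gam, newdata = md$nd[md$valid, , drop = FALSE],
    type = "response")) * 100
  list(density = dd_raster(grid, matrix(dens, grid$nrow, grid$ncol),
                           name = "density", units = "ind per 100 km2"),
       extrapolated = dd_raster(grid,
                                matrix(as.numeric(md$extrap),
                                       grid$nrow, grid$ncol),
                                name = "extrapolated", units = ""))
}

#' Prediction uncertainty map
#'
#' Parametric-bootstrap uncertainty: coefficients are drawn from their
#' asymptotic multivariate normal (mean = estimates, covariance = the
#' Bayesian posterior covariance of the fit), the density map is
#' recomputed per draw, and the per-cell standard deviation of the draws
#' is returned on the density scale (individuals per 100 km^2).
#'
#' @param fit A [fit_tweedie_gam()] result.
#' @param covariates,grid As in [predict_map()].
#' @param n_draws Number of coefficient draws (default 200).
#' @param seed Integer seed.
#' @return A [dd_raster()] of per-cell prediction sd.
#' @export
predict_uncertainty <- function(fit, covariates, grid, n_draws = 200,
                                seed = 1) {
  md <- map_newdata(fit, covariates, grid)
  Vp <- fit$gam$Vp
  if (any(!is.finite(Vp)) || rcond_psd(Vp) == 0)
    stop("singular coefficient covariance")
  X <- stats::predict(fit$gam, newdata = md$nd[md$valid, , drop = FALSE],
                      type = "lpmatrix")
  draws <- withr::with_seed(as.integer(seed),
    mgcv::rmvn(n_draws, as.numeric(stats::coef(fit$gam)), Vp))
  eta <- X %*% t(draws)           # cells x draws, offset 0 at unit area
  sdv <- apply(exp(eta) * 100, 1, stats::sd)
  out <- rep(NA_real_, nrow(md$nd))
  out[md$valid] <- sdv
  dd_raster(grid, matrix(out, grid$nrow, grid$ncol),
            name = "uncertainty_sd", units = "ind per 100 km2")
}

rcond_psd <- function(V) {
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  max(min(ev), 0) / max(ev)
}
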