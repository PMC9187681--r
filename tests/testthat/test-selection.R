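toy_corr <- function(vars, pairs = list()) {
  C <- diag(length(vars))
  dimnames(C) <- list(vars, vars)
  for (p in pairs) { C[p[[1]], p[[2]]] <- p[[3]]; C[p[[2]], p[[1]]] <- p[[3]] }
  C
}

test_that("correlation matrix matches the textbook Pearson formula", {
  set.seed(101)
  tab <- data.frame(a = rnorm(200), b = rnorm(200), c = rnorm(200))
  tab$d <- 2 * tab$a + 1  # exact linear function
  C <- correlation_matrix(tab, c("a", "b", "c", "d"))
  expect_equal(C["a", "d"], 1, tolerance = 1e-12)
  expect_equal(diag(C), c(a = 1, b = 1, c = 1, d = 1))
  expect_equal(C, t(C))
  pearson <- function(x, y) {
    n <- length(x)
    (sum(x * y) - n * mean(x) * mean(y)) /
      sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  }
  for (v in c("b", "c")) expect_equal(C["a", v], pearson(tab$a, tab[[v]]),
                                      tolerance = 1e-12)
  # independent columns at n = 1e4 have |r| < 0.05
  set.seed(102)
  big <- data.frame(x = rnorm(1e4), y = rnorm(1e4))
  expect_lt(abs(correlation_matrix(big, c("x", "y"))["x", "y"]), 0.05)
  # zero-variance columns are flagged and treated as uncorrelated
  tab$z <- 1
  Cz <- correlation_matrix(tab, c("a", "z"))
  expect_equal(attr(Cz, "zero_variance"), "z")
  expect_equal(Cz["a", "z"], 0)
})

test_that("candidate enumeration filters correlated pairs exactly", {
  # 3 mutually uncorrelated variables: all 7 non-empty subsets of size <= 4
  C <- toy_corr(c("a", "b", "c"))
  expect_length(enumerate_candidates(c("a", "b", "c"), C), 7)
  # planted |r| = 0.9 pair removes every subset containing both
  C <- toy_corr(c("a", "b", "c"), list(list("a", "b", 0.9)))
  sets <- enumerate_candidates(c("a", "b", "c"), C)
  expect_equal(sets, list("a", "b", "c", c("a", "c"), c("b", "c")))
  # boundary: |r| exactly at the threshold is allowed
  C <- toy_corr(c("a", "b"), list(list("a", "b", 0.5)))
  expect_length(enumerate_candidates(c("a", "b"), C), 3)
  C <- toy_corr(c("a", "b"), list(list("a", "b", -0.51)))
  expect_length(enumerate_candidates(c("a", "b"), C), 2)
  expect_error(enumerate_candidates(character(0), C), "empty")
})

test_that("enumeration equals the brute-force power-set filter", {
  set.seed(103)
  vars <- paste0("v", sprintf("%02d", 1:10))
  C <- toy_corr(vars, list(list("v02", "v07", 0.8), list("v01", "v04", -0.6),
                           list("v03", "v05", 0.5)))
  got <- enumerate_candidates(vars, C, max_size = 4, threshold = 0.5)
  want <- oracle_enumerate(vars, C, max_size = 4, threshold = 0.5)
  expect_equal(got, want)
  # 28 uncorrelated variables: C(28,1) + ... + C(28,4) = 24157 subsets
  vars28 <- paste0("w", sprintf("%02d", 1:28))
  C28 <- toy_corr(vars28)
  expect_length(enumerate_candidates(vars28, C28),
                choose(28, 1) + choose(28, 2) + choose(28, 3) + choose(28, 4))
})

test_that("Akaike weights: closed forms, normalisation, shift invariance", {
  expect_equal(akaike_weights(42), 1)
  expect_equal(akaike_weights(c(100, 100)), c(0.5, 0.5))
  # AICs {100, 102}: w = {1/(1+e^-1), e^-1/(1+e^-1)} = {0.7311, 0.2689}
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(round(w, 4), c(0.7311, 0.2689))
  set.seed(104)
  aics <- runif(50, 200, 260)
  w <- akaike_weights(aics)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(w, akaike_weights(aics + 1234.5), tolerance = 1e-12)
  expect_true(all(w >= 0 & w <= 1))
  # infinite AICs get zero weight; all-infinite errors
  expect_equal(akaike_weights(c(100, Inf))[2], 0)
  expect_error(akaike_weights(c(Inf, Inf)), "infinite")
})

test_that("summed-weight importance: examples, identity, brute force", {
  mk <- function(sets, w) {
    structure(list(sets = sets,
                   records = data.frame(weight = w)), class = "dd_candidates")
  }
  # worked example: x in A and B, y in B and C
  imp <- variable_importance(mk(list("x", c("x", "y"), "y"),
                               c(0.4, 0.35, 0.25)))
  expect_equal(imp$importance[imp$variable == "x"], 0.75)
  expect_equal(imp$importance[imp$variable == "y"], 0.60)
  expect_equal(imp$variable, c("x", "y"))  # ranked by importance
  # a variable present in every model has importance 1
  imp2 <- variable_importance(mk(list("a", c("a", "b")), c(0.7, 0.3)))
  expect_equal(imp2$importance[imp2$variable == "a"], 1)
  # random records: brute-force double loop + double-count identity
  set.seed(105)
  vars <- paste0("v", 1:8)
  sets <- replicate(40, sample(vars, sample(1:4, 1)), simplify = FALSE)
  w <- akaike_weights(runif(40, 100, 120))
  imp3 <- variable_importance(mk(sets, w))
  for (v in unique(unlist(sets))) {
    brute <- 0
    for (i in seq_along(sets)) if (v %in% sets[[i]]) brute <- brute + w[i]
    expect_equal(imp3$importance[imp3$variable == v], brute,
                 tolerance = 1e-12)
  }
  expect_equal(sum(imp3$importance), sum(w * lengths(sets)),
               tolerance = 1e-12)
  expect_true(all(imp3$importance >= 0 & imp3$importance <= 1))
})

test_that("top-uncorrelated selection walks the ranking greedily", {
  imp <- data.frame(variable = c("a", "b", "c", "d", "e"),
                    importance = c(0.9, 0.8, 0.6, 0.5, 0.4),
                    rank = 1:5)
  # b correlated with a -> skipped, next uncorrelated ones taken
  C <- toy_corr(c("a", "b", "c", "d", "e"), list(list("a", "b", 0.8)))
  expect_equal(select_top_uncorrelated(imp, C), c("a", "c", "d", "e"))
  # all uncorrelated -> top four of the ranking
  C0 <- toy_corr(c("a", "b", "c", "d", "e"))
  expect_equal(select_top_uncorrelated(imp, C0), c("a", "b", "c", "d"))
  expect_equal(select_top_uncorrelated(imp, C0, n = 2), c("a", "b"))
})

test_that("the published importance ranking reproduces the final variable set", {
  # printed summed-weight ranking for the beaked-whale analysis, with
  # roughness and slope known to be correlated: the final set skips slope
  imp <- data.frame(
    variable = c("mT_surface", "sdT_0_200", "Roughness", "Slope", "Depth",
                 "CanArea"),
    importance = c(0.856, 0.700, 0.384, 0.361, 0.280, 0.199))
  imp$rank <- seq_len(nrow(imp))
  C <- toy_corr(imp$variable, list(list("Roughness", "Slope", 0.8)))
  expect_equal(select_top_uncorrelated(imp, C),
               c("mT_surface", "sdT_0_200", "Roughness", "Depth"))
})

test_that("ensemble membership and averaging follow the cumulative-weight rule", {
  g <- dd_grid(-5, -4, 44, 45, res = 0.25)
  # real intercept-only fits with different mean densities: constant maps
  truth <- default_test_truth(actives = "x01", shapes = c(x01 = "flat"))
  mk_fit <- function(intercept, seed) {
    tr <- default_test_truth(actives = "x01", shapes = c(x01 = "flat"),
                             intercept = intercept)
    tab <- sim_segment_table(300, 1, seed = seed, tr)
    tab <- generate_counts(tr, tab, seed = seed + 1)
    fit_tweedie_gam(tab, character(0), p = 1.4)
  }
  fits <- list(mk_fit(log(0.30), 201), mk_fit(log(0.10), 203),
               mk_fit(log(0.03), 205), mk_fit(log(0.01), 207))
  levels <- vapply(fits, function(f)
    100 * exp(unname(coef(f$gam)[1])), 0)
  cands_for <- function(w) structure(
    list(records = data.frame(weight = w,
                              variables = paste0("m", seq_along(w))),
         fits = fits[seq_along(w)], sets = as.list(paste0("m", seq_along(w)))),
    class = "dd_candidates")
  ens <- ensemble_average(cands_for(c(0.5, 0.3, 0.15, 0.05)), list(), g)
  expect_length(ens$members, 2)
  expect_equal(ens$weights, c(0.5, 0.3) / 0.8, tolerance = 1e-12)
  # weighted mean of the member constant maps, renormalised weights
  expect_equal(ens$density$values[1, 1],
               sum(c(0.5, 0.3) / 0.8 * levels[1:2]), tolerance = 1e-8)
  expect_length(ensemble_average(cands_for(c(0.85, 0.1, 0.05)),
                                 list(), g)$members, 1)
  # uniform weights: 0.75 < 0.8 at three members, so all four are needed
  expect_length(ensemble_average(cands_for(rep(0.25, 4)),
                                 list(), g)$members, 4)
})

test_that("R2 comparison is scale-free and handles degenerate maps", {
  g <- dd_grid(-6, -4, 44, 46, res = 0.05)
  set.seed(106)
  a <- dd_raster(g, matrix(rexp(prod(dim(g))), g$nrow, g$ncol))
  same <- compare_r2(a, a)
  expect_equal(same$r2, 1, tolerance = 1e-12)
  expect_true(same$pass)
  doubled <- compare_r2(a, dd_raster(g, 2 * a$values))
  expect_equal(doubled$r2, 1, tolerance = 1e-12)
  # independent noise: R2 near zero on 10^4 cells
  b <- dd_raster(g, matrix(rexp(prod(dim(g))), g$nrow, g$ncol))
  expect_gt(prod(dim(g)), 1e3)
  noise <- compare_r2(a, b)
  expect_lt(noise$r2, 0.05)
  expect_false(noise$pass)
  const <- compare_r2(a, dd_raster(g, 3))
  expect_true(const$constant)
  expect_true(is.na(const$r2))
  g2 <- dd_grid(-6, -4, 44, 46, res = 0.5)
  expect_error(compare_r2(a, dd_raster(g2, 1)), "different grids")
})
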