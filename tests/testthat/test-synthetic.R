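test_that("bathymetry has shelf, abyssal plain and is seed-deterministic", {
  cfg <- scenario_config(seed = 5)
  b <- generate_bathymetry(cfg)
  expect_true(min(b$values) >= 0)
  expect_true(max(b$values) > 2000)
  # shelf in the east (shallow), abyssal in the west (deep)
  expect_true(mean(b$values[, ncol(b$values)]) < 200)
  expect_true(mean(b$values[, 1]) > 2000)
  # shelf widens northward: the 200 m isobath sits further west in the north
  shelf_edge_col <- function(i) min(which(b$values[i, ] < 200))
  expect_true(shelf_edge_col(1) < shelf_edge_col(nrow(b$values)))
  b2 <- generate_bathymetry(cfg)
  expect_identical(b$values, b2$values)
  b3 <- generate_bathymetry(scenario_config(seed = 6))
  expect_false(identical(b$values, b3$values))
})

test_that("canyon-area raster has the configured number of channels", {
  for (nc in c(2L, 3L, 5L)) {
    cfg <- scenario_config(seed = 9, n_canyons = nc)
    b <- generate_bathymetry(cfg)
    ca <- generate_canyon_area(b, cfg)
    expect_equal(oracle_n_components(ca$values > 0), nc)
  }
})

test_that("canyon area is the painted spherical cell area, zero elsewhere", {
  cfg <- scenario_config(seed = 9, n_canyons = 3)
  b <- generate_bathymetry(cfg)
  ca <- generate_canyon_area(b, cfg)
  expect_true(all(ca$values >= 0))
  mask <- attr(b, "canyon_mask")
  areas <- cell_area_km2(b$grid)
  expect_equal(sum(ca$values), sum(areas[mask]), tolerance = 1e-12)
  expect_true(all(ca$values[!mask] == 0))
  # no canyons configured -> all-zero raster
  cfg0 <- scenario_config(seed = 9, n_canyons = 0)
  ca0 <- generate_canyon_area(generate_bathymetry(cfg0), cfg0)
  expect_true(all(ca0$values == 0))
})

test_that("dynamic stacks impose the depth trend and the shelf mask", {
  cfg <- small_scenario(seed = 3)
  b <- generate_bathymetry(cfg)
  st <- generate_dynamic_stacks(cfg, b)
  expect_true(mean(st$surface$T$values, na.rm = TRUE) >
              mean(st[["600_2000"]]$T$values, na.rm = TRUE))
  # any shelf cell shallower than 200 m must be missing in the 200-600 stack
  shelf <- which(b$values < 200, arr.ind = TRUE)
  expect_true(nrow(shelf) > 0)
  layer <- st[["200_600"]]$T$values[, , 1]
  expect_true(all(is.na(layer[shelf])))
  # surface stack has no mask
  expect_false(any(is.na(st$surface$T$values)))
  # determinism
  st2 <- generate_dynamic_stacks(cfg, b)
  expect_identical(st$surface$T$values, st2$surface$T$values)
})

test_that("random-field variogram range recovers the configured length scale", {
  set.seed(42)
  L <- 10
  f <- sim_grf(100, 100, length_scale = L)
  h <- 1:25
  gamma_h <- sapply(h, function(d)
    0.5 * mean((f[, (d + 1):100] - f[, 1:(100 - d)])^2))
  fit <- stats::nls(gamma_h ~ s * (1 - exp(-(h / a)^2)),
                    start = list(s = 1, a = 8))
  a_hat <- coef(fit)[["a"]]
  expect_lt(abs(a_hat - L) / L, 0.25)
  # marginal variance near 1
  expect_equal(stats::sd(as.vector(f)), 1, tolerance = 0.15)
})

test_that("effort generator respects ESW bounds, Beaufort support and total length", {
  cfg <- scenario_config(seed = 13)
  eff <- generate_effort(cfg)
  expect_true(all(eff$esw_table$esw_km > 0 & eff$esw_table$esw_km <= 2))
  expect_equal(nrow(eff$esw_table), 2 * 5 * 2)  # platform x beaufort x height
  b <- eff$tracklines$attrs$beaufort
  expect_true(all(b >= 0 & b <= 7))
  # strip surveys are ship-based
  strip <- eff$tracklines$attrs$survey_type == "strip"
  expect_true(all(eff$tracklines$attrs$platform[strip] == "ship"))
  tot <- sum(vapply(eff$tracklines$coords, function(m) {
    d <- geosphere::distHaversine(m[-nrow(m), ], m[-1, ]) / 1000
    sum(d)
  }, 0))
  expect_lt(abs(tot - cfg$effort$total_length_km) / cfg$effort$total_length_km,
            0.01)
})

test_that("compound Poisson-gamma draws have Tweedie moments", {
  set.seed(3)
  mu <- 2; p <- 1.4; phi <- 1.5
  y <- rtweedie_cpg(2e5, mu, p, phi)
  expect_equal(mean(y), mu, tolerance = 0.01)
  # variance / mean^p ratio recovers the dispersion
  expect_equal(var(y) / mu^p, phi, tolerance = 0.05)
  # zero mass matches the closed-form Poisson(0) probability
  lambda <- mu^(2 - p) / (phi * (2 - p))
  expect_equal(mean(y == 0), exp(-lambda), tolerance = 0.01)
  # independent oracle: mgcv's compound Poisson-gamma sampler
  set.seed(4)
  y_ref <- mgcv::rTweedie(rep(mu, 2e5), p = p, phi = phi)
  expect_equal(mean(y), mean(y_ref), tolerance = 0.02)
  expect_equal(var(y), var(y_ref), tolerance = 0.05)
  expect_error(rtweedie_cpg(10, 1, p = 2.5, phi = 1), "p < 2")
})

test_that("sampler distribution matches the series-evaluated Tweedie density", {
  mu <- 2; p <- 1.4; phi <- 1.5
  set.seed(6)
  y <- rtweedie_cpg(1e5, mu, p, phi)
  # CDF from the Dunn-Smyth series density: point mass at zero plus a
  # numerical integral of the continuous branch
  p0 <- exp(-mu^(2 - p) / (phi * (2 - p)))
  dens <- function(t) exp(mgcv::ldTweedie(t, mu = mu, p = p, phi = phi)[, 1])
  for (y0 in c(0.5, 1, 2, 4, 8)) {
    cdf <- p0 + stats::integrate(dens, 1e-12, y0, rel.tol = 1e-8)$value
    expect_equal(mean(y <= y0), cdf, tolerance = 0.01)
  }
})

test_that("ground-truth counts have the closed-form mean and respect areas", {
  # flat smooths, intercept log(0.01) per km2, area 12 km2 -> mean 0.12
  tm <- true_model(active_variables = "x", smooth_shapes = c(x = "flat"),
                   intercept = log(0.01), tweedie_p = 1.4, dispersion = 0.05)
  seg <- data.frame(id = seq_len(1e5), effective_area = 12, x = rnorm(1e5))
  seg <- generate_counts(tm, seg, seed = 2)
  expect_true(all(seg$count == floor(seg$count)))
  se <- sd(seg$count) / sqrt(nrow(seg))
  expect_lt(abs(mean(seg$count) - 0.12), 3 * se)
  # zero effective area -> zero counts, always
  seg0 <- data.frame(id = 1:500, effective_area = 0, x = rnorm(500))
  expect_true(all(generate_counts(tm, seg0, seed = 5)$count == 0))
  # two seeds: different draws, same expectation within Monte-Carlo error
  sega <- generate_counts(tm, seg[1:5e4, ], seed = 10)
  segb <- generate_counts(tm, seg[1:5e4, ], seed = 11)
  expect_false(identical(sega$count, segb$count))
  tt <- t.test(sega$count, segb$count)
  expect_gt(tt$p.value, 0.001)
  # same seed -> identical
  expect_identical(generate_counts(tm, seg[1:100, ], seed = 7)$count,
                   generate_counts(tm, seg[1:100, ], seed = 7)$count)
})

test_that("counts generator names the offending segment on missing covariates", {
  tm <- true_model(active_variables = "x", smooth_shapes = c(x = "flat"))
  seg <- data.frame(id = 101:110, effective_area = 10, x = rnorm(10))
  seg$x[4] <- NA
  expect_error(generate_counts(tm, seg, seed = 1), "104")
  expect_error(generate_counts(tm, seg[, c("id", "effective_area")], seed = 1),
               "missing covariate")
})

test_that("vertical averaging weights levels by slab thickness", {
  g <- dd_grid(0, 1, 0, 1, res = 0.5)
  lv <- list(dd_raster(g, 10), dd_raster(g, 20), dd_raster(g, 40))
  out <- vertical_average(lv, depths = c(100, 300, 500), d1 = 0, d2 = 600)
  # slabs: 0-200 (10), 200-400 (20), 400-600 (40) -> equal thirds
  expect_equal(out$values[1, 1], (10 + 20 + 40) / 3)
  expect_error(vertical_average(lv, c(100, 300, 500), 700, 800), "no levels")
})

test_that("scenario YAML round-trips the configuration", {
  cfg <- scenario_config(seed = 21, n_months = 6, n_canyons = 4)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_yaml(cfg, f)
  cfg2 <- read_scenario_yaml(f)
  expect_equal(cfg2$seed, cfg$seed)
  expect_equal(unclass(cfg2$grid), unclass(cfg$grid), tolerance = 1e-12)
  expect_equal(cfg2$truth$active_variables, cfg$truth$active_variables)
  expect_equal(cfg2$effort$total_length_km, cfg$effort$total_length_km)
  # identical generated bathymetry from the round-tripped config
  expect_identical(generate_bathymetry(cfg)$values,
                   generate_bathymetry(cfg2)$values)
})
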