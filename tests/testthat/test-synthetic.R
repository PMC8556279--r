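test_that("noise-free non-spatial limit returns exactly X beta plus base level", {
  g <- make_lattice(4, 4, 50)
  p <- dgp_params(beta = c(x1 = 1, x2 = -2), lambda = 0, rho = 0,
                  sigma_nu = 0, sigma_alpha = 0, gamma_alpha = 0,
                  base_level = 20, covariates = covfun_iid, seed = 5)
  pan <- simulate_panel(g, 2001:2003, p)
  expect_equal(pan$pm25, 20 + pan$x1 - 2 * pan$x2, tolerance = 1e-12)
})

test_that("spatial multiplier closed form: constant X, beta 1, lambda 0.5 gives y = 2", {
  g <- make_lattice(5, 5, 50)
  w <- quick_weights(5, 5)
  ones <- function(geom, years)
    data.frame(county_id = rep(geom$county_id, length(years)),
               year = rep(years, each = length(geom$county_id)), ones = 1)
  p <- dgp_params(beta = c(ones = 1), lambda = 0.5, rho = 0, sigma_nu = 0,
                  sigma_alpha = 0, gamma_alpha = 0, base_level = 0,
                  covariates = ones, seed = 1)
  pan <- simulate_panel(g, 2001:2002, p, w)
  expect_equal(pan$pm25, rep(2, nrow(pan)), tolerance = 1e-12)
})

test_that("identical seeds reproduce identical panels", {
  g <- make_lattice(4, 4, 50)
  w <- quick_weights(4, 4)
  p <- dgp_params(seed = 99)
  pan1 <- simulate_panel(g, 2003:2006, p, w)
  pan2 <- simulate_panel(g, 2003:2006, p, w)
  expect_identical(pan1, pan2)
  p2 <- dgp_params(seed = 100)
  expect_false(identical(simulate_panel(g, 2003:2006, p2, w)$pm25, pan1$pm25))
})

test_that("simultaneous solve agrees with the truncated 500-term power series", {
  for (lambda in c(0.3, 0.8)) {
    g <- make_lattice(10, 10, 10)
    w <- quick_weights(10, 10, 10)
    W <- weights_matrix(w)
    v <- rnorm(100)
    exact <- as.numeric(Matrix::solve(Matrix::Diagonal(100) - lambda * W, v))
    acc <- v; cur <- v
    for (s in 1:500) { cur <- lambda * as.numeric(W %*% cur); acc <- acc + cur }
    expect_lt(max(abs(acc - exact)) / max(abs(exact)), 1e-8)
  }
})

test_that("default generator respects physical ranges", {
  g <- make_lattice(6, 6, 50)
  w <- quick_weights(6, 6)
  pan <- simulate_panel(g, 2003:2010, dgp_params(seed = 17), w)
  validate_panel(pan)
  expect_true(all(pan$pm25 >= 0))
  expect_true(all(pan$co2_per_km2 >= 0))
  pct <- grep("_pct$", names(pan), value = TRUE)
  for (cc in pct) expect_true(all(pan[[cc]] >= 0 & pan[[cc]] <= 100))
  # balanced by construction
  expect_true(all(table(pan$county_id, pan$year) == 1L))
})

test_that("stationarity violations and unbalanced covariates are rejected", {
  g <- make_lattice(3, 3, 50)
  w <- quick_weights(3, 3)
  expect_error(dgp_params(lambda = 1), "stationarity")
  expect_error(dgp_params(rho = -1.2), "stationarity")
  short <- function(geom, years) covfun_iid(geom, years)[-1, ]
  p <- dgp_params(beta = c(x1 = 1, x2 = 1), covariates = short, seed = 1)
  expect_error(simulate_panel(g, 2001:2004, p, w), "unbalanced")
})

test_that("varying mode records true surfaces and evaluates them at centroids", {
  g <- make_lattice(5, 5, 50)
  p <- dgp_params(mode = "varying-coefficients", sigma_nu = 0, seed = 31)
  pan <- simulate_panel(g, 2003:2006, p)
  tr <- attr(pan, "true_coefficients")
  expect_equal(nrow(tr), nrow(pan))
  # noise-free outcome reproduces the surface arithmetic row by row
  recon <- tr[["(Intercept)"]] + tr$co2_z * pan$co2_z + tr$popden_z * pan$popden_z
  expect_equal(pan$pm25, recon, tolerance = 1e-12)
  # smoothness: neighbouring years differ little
  s <- default_coefficient_surface(g, 2003:2006)
  b1 <- s(125, 125, 2003); b2 <- s(125, 125, 2004)
  expect_lt(abs(b1[["co2_z"]] - b2[["co2_z"]]), 0.1)
})

test_that("linear interpolation hits interior years, anchors, and constant series", {
  out <- interpolate_missing_years(data.frame(year = c(2001, 2004),
                                              value = c(10, 16)), 2001:2004)
  expect_equal(out$value, c(10, 12, 14, 16))
  anch <- data.frame(year = c(2001, 2006, 2011), value = c(5, 10, 3))
  at_anchors <- interpolate_missing_years(anch, anch$year)
  expect_equal(at_anchors$value, anch$value)
  const <- interpolate_missing_years(data.frame(year = c(2013, 2016),
                                                value = c(5, 5)), 2014)
  expect_equal(const$value, 5)
  # outside the anchor range: nearest-anchor constant extrapolation
  ext <- interpolate_missing_years(data.frame(year = c(2004, 2006),
                                              value = c(8, 12)), 2001:2008)
  expect_equal(ext$value[1:3], rep(8, 3))
  expect_equal(ext$value[7:8], rep(12, 2))
  expect_error(interpolate_missing_years(data.frame(year = 2004, value = 8),
                                         2001:2008), "2 anchors")
})

test_that("baseline mortality draws honour rate, total, and seed", {
  g <- make_lattice(10, 10, 50)
  w <- quick_weights(10, 10)
  pan <- simulate_panel(g, 2003:2012, dgp_params(seed = 8), w)
  zero <- simulate_baseline_mortality(pan, 2010, total_deaths = 0, seed = 1)
  expect_true(all(zero$map_deaths == 0))
  m1 <- simulate_baseline_mortality(pan, 2010, total_deaths = 54730, seed = 2)
  expect_equal(unique(m1$year), 2010)
  # national total within Poisson sampling error (about 4 sd)
  expect_lt(abs(sum(m1$map_deaths) - 54730), 4 * sqrt(54730))
  m2 <- simulate_baseline_mortality(pan, 2010, total_deaths = 54730, seed = 2)
  expect_identical(m1, m2)
  expect_error(simulate_baseline_mortality(pan, 1999, seed = 1), "range")
})
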