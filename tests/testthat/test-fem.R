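test_that("within estimator recovers coefficients exactly on noise-free data", {
  g <- make_lattice(5, 5, 50)
  p <- dgp_params(beta = c(x1 = 1, x2 = -2), lambda = 0, rho = 0,
                  sigma_nu = 0, sigma_alpha = 1, gamma_alpha = 0,
                  base_level = 20, covariates = covfun_iid, seed = 3)
  pan <- simulate_panel(g, 2001:2005, p)
  f <- fit_fem(pan, spec_iid())
  expect_equal(f$coefficients$estimate, c(1, -2), tolerance = 1e-10)
  # fixed effects recovered
  expect_equal(unname(f$fixed_effects), unname(attr(pan, "fixed_effects")),
               tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  # residuals mean-zero within each county
  by_cty <- tapply(f$residuals, f$design$panel$county_id, mean)
  expect_true(all(abs(by_cty) < 1e-10))
})

test_that("within transform is invariant to county-level shifts of y", {
  g <- make_lattice(4, 4, 50)
  pan <- sim_iid_panel(g, 2001:2006, NULL, 0, 0, seed = 12)
  f1 <- fit_fem(pan, spec_iid())
  shifted <- pan
  target <- unique(pan$county_id)[3]
  shifted$pm25[shifted$county_id == target] <-
    shifted$pm25[shifted$county_id == target] + 11
  f2 <- fit_fem(shifted, spec_iid())
  expect_equal(f2$coefficients$estimate, f1$coefficients$estimate,
               tolerance = 1e-10)
  expect_equal(unname(f2$fixed_effects[target] - f1$fixed_effects[target]), 11,
               tolerance = 1e-10)
})

test_that("rank-deficient designs name the collinear columns", {
  g <- make_lattice(3, 3, 50)
  pan <- sim_iid_panel(g, 2001:2004, NULL, 0, 0, seed = 4)
  pan$x3 <- pan$x1 + pan$x2
  expect_error(fit_fem(pan, model_spec(regressors = c("x1", "x2", "x3"))),
               "x3")
})

test_that("omitted spatial lag biases the within estimator while the SAC fit recovers it", {
  set.seed(71)
  g <- make_lattice(10, 10, 50)
  w <- quick_weights(10, 10)
  reps <- 12
  fem_b <- sac_b <- numeric(reps)
  for (r in seq_len(reps)) {
    # lag in the DGP plus a spatially structured regressor so the omitted
    # multiplier contaminates the naive estimate
    n <- 100; T <- 6
    xs <- function(geom, years) {
      base <- as.numeric(scale(geom$x + geom$y)) + rnorm(100, 0, 0.5)
      data.frame(county_id = rep(geom$county_id, length(years)),
                 year = rep(years, each = 100),
                 x1 = rep(base, length(years)) + rnorm(100 * length(years)))
    }
    p <- dgp_params(beta = c(x1 = 1), lambda = 0.6, rho = 0, sigma_nu = 1,
                    sigma_alpha = 1, gamma_alpha = 0, base_level = 25,
                    covariates = xs, seed = 700 + r)
    pan <- simulate_panel(g, 2001:2006, p, w)
    spec1 <- model_spec(regressors = "x1")
    fem_b[r] <- fit_fem(pan, spec1)$coefficients$estimate
    sac_b[r] <- fit_spatial_panel(pan, w, spec1, "lag")$coefficients$estimate
  }
  expect_lt(abs(mean(sac_b) - 1), 0.05)
  expect_gt(abs(mean(fem_b) - 1), abs(mean(sac_b) - 1) + 0.02)
})

test_that("pooling tests hold size without individual effects and gain power with them", {
  g <- make_lattice(7, 7, 50)
  reps <- 200
  rej <- matrix(FALSE, reps, 3,
                dimnames = list(NULL, c("f_null", "bp_null", "f_alt")))
  for (r in seq_len(reps)) {
    null_pan <- sim_iid_panel(g, 2001:2005, NULL, 0, 0, sigma_alpha = 0,
                              seed = 2000 + r)
    dn <- panel_diagnostics(null_pan, spec_iid())
    rej[r, "f_null"] <- dn$f_individual$p_value < 0.05
    rej[r, "bp_null"] <- dn$bp_lm$p_value < 0.05
    alt_pan <- sim_iid_panel(g, 2001:2005, NULL, 0, 0, sigma_alpha = 5,
                             seed = 4000 + r)
    rej[r, "f_alt"] <- panel_diagnostics(alt_pan, spec_iid())$f_individual$p_value < 0.05
  }
  rate <- colMeans(rej)
  expect_gt(rate[["f_null"]], 0.01); expect_lt(rate[["f_null"]], 0.10)
  expect_gt(rate[["bp_null"]], 0.01); expect_lt(rate[["bp_null"]], 0.10)
  expect_gt(rate[["f_alt"]], 0.95)
})

test_that("Hausman test detects fixed effects correlated with a regressor", {
  g <- make_lattice(10, 10, 50)
  reps <- 25
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    set.seed(6000 + r)
    # alpha loads on the county mean of x1
    n <- 100; T <- 10
    base <- rnorm(n)
    covf <- function(geom, years)
      data.frame(county_id = rep(geom$county_id, T),
                 year = rep(years, each = n),
                 x1 = rep(base, T) + rnorm(n * T),
                 x2 = rnorm(n * T))
    p <- dgp_params(beta = c(x1 = 1, x2 = -2), lambda = 0, rho = 0,
                    sigma_nu = 1, sigma_alpha = 0.1, gamma_alpha = 0,
                    base_level = 25, covariates = covf, seed = 6000 + r)
    pan <- simulate_panel(g, 2001:2010, p)
    pan$pm25 <- pan$pm25 + rep(1.5 * base, T)   # correlated county effect
    rej[r] <- panel_diagnostics(pan, spec_iid())$hausman$p_value < 0.05
  }
  expect_gt(mean(rej), 0.9)
})

test_that("robust LM pair holds size under the null and detects its own alternative", {
  g <- make_lattice(7, 7, 50)
  w <- quick_weights(7, 7)
  reps <- 150
  rej <- matrix(FALSE, reps, 4,
                dimnames = list(NULL, c("lag0", "err0", "lagA", "errA")))
  for (r in seq_len(reps)) {
    pan0 <- sim_iid_panel(g, 2001:2005, w, 0, 0, seed = 8000 + r)
    t0 <- robust_lm_tests(fit_fem(pan0, spec_iid()), w)
    rej[r, "lag0"] <- t0$robust_lm_lag$p_value < 0.05
    rej[r, "err0"] <- t0$robust_lm_error$p_value < 0.05
    panL <- sim_iid_panel(g, 2001:2005, w, 0.7, 0, seed = 9000 + r)
    rej[r, "lagA"] <- robust_lm_tests(fit_fem(panL, spec_iid()),
                                      w)$robust_lm_lag$p_value < 0.05
    panE <- sim_iid_panel(g, 2001:2005, w, 0, 0.7, seed = 10000 + r)
    rej[r, "errA"] <- robust_lm_tests(fit_fem(panE, spec_iid()),
                                      w)$robust_lm_error$p_value < 0.05
  }
  rate <- colMeans(rej)
  expect_gt(rate[["lag0"]], 0.01); expect_lt(rate[["lag0"]], 0.11)
  expect_gt(rate[["err0"]], 0.01); expect_lt(rate[["err0"]], 0.11)
  expect_gt(rate[["lagA"]], 0.9)
  expect_gt(rate[["errA"]], 0.9)
})

test_that("the decision tree recommends each model where its tests point", {
  mk <- function(f, bp, h, lag = NULL, err = NULL) {
    d <- structure(list(
      f_individual = list(statistic = 1, p_value = f),
      bp_lm = list(statistic = 1, p_value = bp),
      hausman = list(statistic = 1, p_value = h)), class = "panel_diagnostics")
    r <- if (is.null(lag)) NULL else structure(list(
      robust_lm_lag = list(statistic = 1, p_value = lag),
      robust_lm_error = list(statistic = 1, p_value = err)),
      class = "panel_diagnostics")
    recommend_model(d, r)
  }
  expect_equal(mk(0.5, 0.5, 0.5), "OLS")
  expect_equal(mk(1e-9, 1e-9, 0.5), "REM")
  expect_equal(mk(1e-9, 1e-9, 1e-9), "FEM")
  expect_equal(mk(1e-9, 1e-9, 1e-9, 1e-9, 0.5), "SPAM")
  expect_equal(mk(1e-9, 1e-9, 1e-9, 0.5, 1e-9), "SPEM")
  expect_equal(mk(1e-9, 1e-9, 1e-9, 1e-9, 1e-9), "SPDM")
})

test_that("panel and weights unit mismatch is caught", {
  g <- make_lattice(4, 4, 50)
  pan <- sim_iid_panel(g, 2001:2004, NULL, 0, 0, seed = 2)
  w_other <- quick_weights(3, 3)
  expect_error(robust_lm_tests(fit_fem(pan, spec_iid()), w_other), "match")
})
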