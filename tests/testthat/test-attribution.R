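test_that("CO2-to-mileage conversion follows from the constants", {
  cc <- conversion_constants()
  expect_equal(co2_to_mileage(404e-6, cc), 1.61)       # one vehicle-mile
  expect_equal(co2_to_mileage(0, cc), 0)
  # one million tons: exact arithmetic oracle, 3.99 Gkm at 3 significant figures
  exact <- 1e6 * 1e6 / 404 * 1.61
  expect_equal(co2_to_mileage(1e6, cc), exact)
  expect_equal(signif(co2_to_mileage(1e6, cc) / 1e9, 3), 3.99)
  expect_error(co2_to_mileage(-1), "nonnegative")
  expect_error(conversion_constants(0, 1.61), "positive")
})

test_that("mileage per unit PM2.5 inverts the coefficient on the exact factor", {
  oracle <- function(beta) (1e12 / 404 * 1.61 / 1e9) / beta
  for (beta in c(0.646, 0.699, 0.593, 2)) {
    expect_equal(mileage_per_unit_pm25(beta), oracle(beta), tolerance = 1e-12)
  }
  expect_equal(signif(mileage_per_unit_pm25(0.646), 3), 6.17)
  expect_equal(signif(mileage_per_unit_pm25(0.699), 3), 5.70)
  # strictly decreasing in beta, tending to zero
  grid <- seq(0.1, 5, by = 0.1)
  vals <- mileage_per_unit_pm25(grid)
  expect_true(all(diff(vals) < 0))
  expect_lt(mileage_per_unit_pm25(1e9), 1e-8)
  expect_error(mileage_per_unit_pm25(0), "positive")
  expect_error(mileage_per_unit_pm25(-0.5), "positive")
})

make_gtwr_stub <- function(df, beta_col = "co2_per_km2") {
  # minimal gtwr_fit carrying the local CO2 coefficients for attribution
  local <- data.frame(county_id = df$county_id, year = df$year)
  local[[beta_col]] <- df$beta
  structure(list(local = local,
                 bandwidth = list(k = 1, tau = 1), r_squared = NA,
                 cv_score = NA, n_ridge_fallbacks = 0L),
            class = "gtwr_fit")
}

test_that("contribution arithmetic and sign handling match the definition", {
  pan <- data.frame(county_id = c("a", "b", "c"), year = 2010,
                    pm25 = c(10, 10, 10), co2_per_km2 = c(2, 1, 1),
                    x = 1, y = 1)
  stub <- make_gtwr_stub(data.frame(county_id = pan$county_id, year = 2010,
                                    beta = c(0.5, 0, -0.2)))
  surf <- contribution(stub, pan)
  expect_equal(surf$con_raw, c(10, 0, -2))
  expect_equal(surf$con_clamped, c(10, 0, 0))
  bad <- pan; bad$pm25[2] <- 0
  expect_error(contribution(stub, bad), "b")
})

test_that("period-mean averaging substitutes the county mean CO2", {
  pan <- data.frame(county_id = rep(c("a", "b"), each = 2),
                    year = rep(2010:2011, 2),
                    pm25 = 10, co2_per_km2 = c(1, 3, 2, 2), x = 1, y = 1)
  stub <- make_gtwr_stub(data.frame(county_id = pan$county_id,
                                    year = pan$year, beta = 0.5))
  surf_year <- contribution(stub, pan, co2_averaging = "yearly")
  surf_mean <- contribution(stub, pan, co2_averaging = "period-mean")
  expect_equal(surf_year$con_raw, c(5, 15, 10, 10))
  expect_equal(surf_mean$con_raw, rep(10, 4))
})

test_that("clamping fixes the band and is idempotent", {
  surf <- data.frame(con_raw = c(-5, 0, 37.765, 100, 150))
  once <- clamp_contribution(surf)
  expect_equal(once$con_clamped, c(0, 0, 37.765, 100, 100))
  expect_equal(clamp_contribution(once)$con_clamped, once$con_clamped)
})

test_that("mortality propagation applies the recursion and its exact inverse", {
  pan <- data.frame(county_id = "a", year = 2009:2011,
                    pm25 = c(9, 10, 11), x = 1, y = 1)
  base <- data.frame(county_id = "a", year = 2010, map_deaths = 1000)
  out <- propagate_mortality(base, pan, cpd = 0.012)
  expect_equal(out$map_deaths[out$year == 2011], 1012)        # dAP = +1
  expect_equal(out$map_deaths[out$year == 2009], 1000 / 1.012)
  # flat concentrations leave the series constant
  flat <- pan; flat$pm25 <- 8
  out2 <- propagate_mortality(base, flat, cpd = 0.012)
  expect_true(all(out2$map_deaths == 1000))
  # degenerate concentration jump
  crash <- pan; crash$pm25 <- c(9, 200, 9)
  expect_error(propagate_mortality(base, crash, cpd = 0.012), "degenerate")
})

test_that("forward-backward propagation round trip returns the anchor to 1e-9", {
  set.seed(10)
  ids <- sprintf("c%02d", 1:12)
  years <- 2003:2009
  pan <- data.frame(county_id = rep(ids, length(years)),
                    year = rep(years, each = length(ids)),
                    pm25 = runif(12 * length(years), 6, 14), x = 1, y = 1)
  base <- data.frame(county_id = ids, year = 2006,
                     map_deaths = runif(12, 50, 500))
  full <- propagate_mortality(base, pan, cpd = 0.012)
  # re-anchor at the last year and propagate back
  tail_anchor <- full[full$year == 2009, ]
  back <- propagate_mortality(tail_anchor, pan, cpd = 0.012)
  merged <- merge(back[back$year == 2006, ], base, by = "county_id")
  expect_lt(max(abs(merged$map_deaths.x - merged$map_deaths.y) /
                merged$map_deaths.y), 1e-9)
})

test_that("attributable deaths respect bounds and total-ratio percentages", {
  mort <- data.frame(county_id = rep(c("a", "b"), 2),
                     year = rep(2010:2011, each = 2),
                     map_deaths = c(100, 300, 200, 600))
  surf <- data.frame(county_id = rep(c("a", "b"), 2),
                     year = rep(2010:2011, each = 2),
                     con_raw = c(10, 50, 0, 100))
  res <- attributable_deaths(mort, clamp_contribution(surf))
  expect_true(all(res$county$mapor_deaths <= res$county$map_deaths))
  expect_true(all(res$county$mapor_deaths >= 0))
  expect_equal(res$yearly$mapor_total, c(160, 600))
  expect_equal(res$yearly$pta_pct, c(160 / 400, 600 / 800) * 100)
  # pooled PTA is the ratio of sums, not the mean of yearly percentages
  expect_equal(res$pta_pooled, (160 + 600) / 1200 * 100)
  expect_false(isTRUE(all.equal(res$pta_pooled, mean(res$yearly$pta_pct))))
  # degenerate extremes
  zero <- surf; zero$con_raw <- 0
  expect_equal(attributable_deaths(mort, clamp_contribution(zero))$pta_pooled, 0)
  all100 <- surf; all100$con_raw <- 100
  r100 <- attributable_deaths(mort, clamp_contribution(all100))
  expect_equal(r100$pta_pooled, 100)
  expect_equal(r100$county$mapor_deaths, mort$map_deaths)
})

test_that("attribution chain is invariant to county reordering", {
  set.seed(4)
  ids <- sprintf("c%02d", 1:10)
  pan <- data.frame(county_id = rep(ids, 3), year = rep(2009:2011, each = 10),
                    pm25 = runif(30, 8, 12), co2_per_km2 = runif(30, 0.01, 0.3),
                    x = 1, y = 1)
  stub <- make_gtwr_stub(data.frame(county_id = pan$county_id, year = pan$year,
                                    beta = runif(30, -0.2, 0.8)))
  base <- data.frame(county_id = ids, year = 2010,
                     map_deaths = rpois(10, 200))
  run_chain <- function(p, b, s) {
    mort <- propagate_mortality(b, p)
    attributable_deaths(mort, clamp_contribution(contribution(s, p)))
  }
  r1 <- run_chain(pan, base, stub)
  shuffle <- sample(nrow(pan))
  pan2 <- pan[shuffle, ]
  r2 <- run_chain(pan2, base[sample(10), ], stub)
  expect_equal(r2$pta_pooled, r1$pta_pooled, tolerance = 1e-12)
  expect_equal(r2$yearly$mapor_total, r1$yearly$mapor_total, tolerance = 1e-12)
})
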