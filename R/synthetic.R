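#' Parameters of the synthetic data-generating process
#'
#' Bundles the true parameters used by [simulate_panel()]. In
#' `"constant-coefficients"` mode the panel outcome solves the combined
#' spatial-lag/spatial-error model
#' \deqn{y_t = \lambda W y_t + X_t\beta + \alpha + u_t,\qquad
#'       u_t = \rho W u_t + \nu_t,}
#' with Gaussian idiosyncratic noise \eqn{\nu_{it}} and Gaussian county fixed
#' effects \eqn{\alpha_i} (constant over time, centred on `base_level`). In
#' `"varying-coefficients"` mode the outcome follows smooth space-time
#' coefficient surfaces \eqn{y_{it} = \beta_0(x,y,t) + \sum_k
#' \beta_k(x,y,t)x_{itk} + \nu_{it}}, the regime the local regression is meant
#' to recover.
#'
#' @param beta named numeric vector of true coefficients; names must match
#'   covariate columns. Ignored in varying mode (the surface supplies them).
#' @param lambda spatial lag parameter, in (-1, 1).
#' @param rho spatial error parameter, in (-1, 1).
#' @param sigma_nu idiosyncratic noise standard deviation (>= 0; 0 gives the
#'   noise-free limiting process used for exact-recovery checks).
#' @param sigma_alpha fixed-effect standard deviation (>= 0).
#' @param gamma_alpha loading of the fixed effects on county urbanization
#'   (the z-score of county-mean log CO2 density, when that column exists).
#'   A nonzero loading makes the unobserved county effect correlated with the
#'   regressors, the situation in which the fixed-effects estimator is
#'   required and the Hausman test rejects random effects; set 0 for
#'   uncorrelated effects.
#' @param base_level mean of the county fixed effects, i.e. the baseline PM2.5
#'   level in micrograms per cubic metre.
#' @param mode `"constant-coefficients"` or `"varying-coefficients"`.
#' @param coefficient_surface for varying mode, `function(x, y, t)` returning
#'   a named vector with an `"(Intercept)"` entry plus one entry per
#'   regressor; `NULL` selects [default_coefficient_surface()].
#' @param covariates `NULL` for the built-in county covariate generator, a
#'   long-format data frame (year-major, one row per county-year), or a
#'   `function(geometry, years)` returning one.
#' @param seed integer seed making the draw reproducible.
#' @return a list of class `dgp_params`.
#' @export
dgp_params <- function(beta = default_true_beta(),
                       lambda = 0.4, rho = 0.3,
                       sigma_nu = 0.5, sigma_alpha = 0.5,
                       gamma_alpha = 0.5,
                       base_level = 1,
                       mode = c("constant-coefficients", "varying-coefficients"),
                       coefficient_surface = NULL,
                       covariates = NULL,
                       seed = NULL) {
  mode <- match.arg(mode)
  if (abs(lambda) >= 1 || abs(rho) >= 1)
    stop("spatial stationarity requires |lambda| < 1 and |rho| < 1")
  if (sigma_nu < 0 || sigma_alpha < 0) stop("noise scales must be nonnegative")
  structure(list(beta = beta, lambda = lambda, rho = rho,
                 sigma_nu = sigma_nu, sigma_alpha = sigma_alpha,
                 gamma_alpha = gamma_alpha,
                 base_level = base_level, mode = mode,
                 coefficient_surface = coefficient_surface,
                 covariates = covariates, seed = seed),
            class = "dgp_params")
}

#' Default true coefficient vector of the constant-coefficient process
#'
#' Magnitudes follow field-typical marginal effects: PM2.5 responds by 0.646
#' micrograms per cubic metre to one unit (1e6 t/km2) of on-road CO2 density,
#' by a few hundredths per percentage point of developed land classes, and
#' weakly to population density and weather.
#' @return named numeric vector.
#' @export
default_true_beta <- function() {
  c(co2_per_km2 = 0.646,
    dev_open_pct = 0.045, dev_low_pct = -0.026, dev_med_pct = 0.030,
    forest_pct = -0.010, grass_pct = -0.008,
    pop_density = 0.300,
    temp_summer = 0.200, temp_winter = 0.100,
    rh_summer = 0.080, rh_winter = 0.050)
}

# County covariate generator: static urban/rural contrasts plus slow yearly
# drift, all in the units the models expect (CO2 in 1e6 t/km2, land cover in
# percent, population density in 1e3 persons/km2, temperatures in K, relative
# humidity in percent). Land-cover series are drawn at the first and last year
# only and filled by interpolate_missing_years(), mirroring how sparse
# land-cover vintages are handled on real data.
default_covariates <- function(geometry, years) {
  n <- n_counties(geometry)
  T <- length(years)
  co2_base <- rlnorm(n, meanlog = log(0.04), sdlog = 1.2)
  pop_base <- rlnorm(n, meanlog = log(0.05), sdlog = 1.0)
  ts_base <- 290 + 8 * geometry$y / max(geometry$y) + rnorm(n, 0, 1.5)
  tw_base <- ts_base - 20 + rnorm(n, 0, 2)
  rs_base <- pmin(95, pmax(5, rnorm(n, 70, 8)))
  rw_base <- pmin(95, pmax(5, rnorm(n, 65, 8)))

  # land-cover composition: 8 tracked classes scaled to 85% of each county
  # (the remainder stands for untracked classes), anchored first/last year
  classes <- c("dev_open_pct", "dev_low_pct", "dev_med_pct", "dev_high_pct",
               "forest_pct", "grass_pct", "crop_pct", "water_pct")
  alpha <- c(2, 2, 1.5, 1, 4, 3, 3, 0.5)
  draw_comp <- function() {
    g <- matrix(rgamma(n * length(classes), shape = rep(alpha, each = n)), nrow = n)
    85 * g / rowSums(g)
  }
  comp0 <- draw_comp()
  drift <- matrix(exp(rnorm(n * length(classes), 0, 0.15)), nrow = n)
  comp1 <- 85 * (comp0 * drift) / rowSums(comp0 * drift)
  lc <- array(0, dim = c(n, T, length(classes)))
  for (i in seq_len(n)) for (k in seq_along(classes)) {
    lc[i, , k] <- interpolate_missing_years(
      data.frame(year = range(years),
                 value = c(comp0[i, k], comp1[i, k])), years)$value
  }

  # yearly weather anomalies: a shared national shock plus smooth spatial
  # gradients, so within-county variation is spatially structured as real
  # meteorology is
  xf <- geometry$x / max(geometry$x); yf <- geometry$y / max(geometry$y)
  anomaly <- function(scale_shared, scale_grad, scale_local)
    rnorm(1, 0, scale_shared) + rnorm(1, 0, scale_grad) * xf +
      rnorm(1, 0, scale_grad) * yf + rnorm(n, 0, scale_local)

  out <- do.call(rbind, lapply(seq_len(T), function(ti) {
    co2 <- co2_base * exp(rnorm(n, 0, 0.08))
    pop <- pop_base * (1.01 ^ (ti - 1)) * exp(rnorm(n, 0, 0.03))
    df <- data.frame(
      county_id = geometry$county_id, year = years[ti],
      co2_per_km2 = co2,
      pop_density = pop,
      temp_summer = ts_base + anomaly(0.5, 0.6, 0.4),
      temp_winter = tw_base + anomaly(0.8, 0.9, 0.6),
      rh_summer = pmin(95, pmax(5, rs_base + anomaly(1.5, 1.5, 1.0))),
      rh_winter = pmin(95, pmax(5, rw_base + anomaly(1.5, 1.5, 1.0)))
    )
    for (k in seq_along(classes)) df[[classes[k]]] <- lc[, ti, k]
    df
  }))
  out$co2_z <- as.numeric(scale(log(out$co2_per_km2)))
  out$popden_z <- as.numeric(scale(log(out$pop_density)))
  rownames(out) <- NULL
  out
}

#' Default smooth coefficient surfaces for the varying-coefficient process
#'
#' Builds a `function(x, y, t)` whose intercept and slopes vary smoothly over
#' the spatial domain (half-period sinusoids across the lattice) and over the
#' year range (one slow cosine cycle). The slopes attach to the standardized
#' covariates `co2_z` and `popden_z`, keeping the local information content
#' comparable across the domain so that surface recovery measures estimator
#' quality rather than covariate scaling.
#'
#' @param geometry lattice geometry (sets the spatial period).
#' @param years year range (sets the temporal period).
#' @return `function(x, y, t)` returning a named coefficient vector.
#' @export
default_coefficient_surface <- function(geometry, years) {
  Lx <- max(geometry$xmax); Ly <- max(geometry$ymax)
  t0 <- min(years); Tr <- max(diff(range(years)), 1)
  function(x, y, t) {
    c("(Intercept)" = 10 + 0.5 * sin(pi * x / Lx) * sin(pi * y / Ly),
      co2_z = 0.30 + 0.25 * sin(pi * x / Lx) * cos(pi * y / Ly) +
        0.10 * cos(pi * (t - t0) / Tr),
      popden_z = 0.20 - 0.20 * cos(pi * x / Lx) * sin(pi * y / Ly))
  }
}

#' Simulate a balanced county-year panel
#'
#' Generates PM2.5 outcomes on a lattice geometry under the process described
#' in [dgp_params()]. Constant mode solves the simultaneous spatial system
#' exactly, `y_t = (I - lambda W)^{-1} (X_t beta + alpha + (I - rho W)^{-1}
#' nu_t)`, year by year; varying mode evaluates the coefficient surfaces at
#' each county centroid and year. The result is year-major (sorted by year,
#' then county) and balanced by construction.
#'
#' @param geometry a `lattice_geometry`.
#' @param years integer vector of consecutive years.
#' @param params a `dgp_params` object.
#' @param weights row-standardized `sp_weights` on `geometry` (required in
#'   constant mode whenever `lambda` or `rho` is nonzero).
#' @return a `county_panel` data frame with columns `county_id`, `year`,
#'   `pm25`, centroids `x`, `y`, and the covariate columns. In varying mode
#'   the true local coefficients are attached as attribute
#'   `"true_coefficients"`.
#' @export
simulate_panel <- function(geometry, years, params, weights = NULL) {
  stopifnot(inherits(params, "dgp_params"))
  if (abs(params$lambda) >= 1 || abs(params$rho) >= 1)
    stop("spatial stationarity requires |lambda| < 1 and |rho| < 1")
  years <- sort(unique(as.integer(years)))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- n_counties(geometry)
  T <- length(years)

  cov_df <- params$covariates
  if (is.null(cov_df)) cov_df <- default_covariates(geometry, years)
  else if (is.function(cov_df)) cov_df <- cov_df(geometry, years)
  if (nrow(cov_df) != n * T)
    stop("covariates must contain one row per county-year (unbalanced request?)")

  if (params$mode == "constant-coefficients") {
    beta <- params$beta
    miss <- setdiff(names(beta), names(cov_df))
    if (length(miss)) stop("beta names missing from covariates: ",
                           paste(miss, collapse = ", "))
    X <- as.matrix(cov_df[names(beta)])
    alpha <- params$base_level + rnorm(n, 0, params$sigma_alpha)
    g <- params$gamma_alpha %||% 0
    if (g != 0 && "co2_per_km2" %in% names(cov_df)) {
      urb <- tapply(log(cov_df$co2_per_km2),
                    factor(cov_df$county_id, levels = geometry$county_id), mean)
      alpha <- alpha + g * as.numeric(scale(as.numeric(urb)))
    }
    need_w <- params$lambda != 0 || params$rho != 0
    if (need_w) {
      if (is.null(weights)) stop("weights are required when lambda or rho is nonzero")
      W <- weights_matrix(weights)
      A <- Matrix::Diagonal(n) - params$lambda * W
      B <- Matrix::Diagonal(n) - params$rho * W
    }
    y <- numeric(n * T)
    for (ti in seq_len(T)) {
      idx <- ((ti - 1) * n + 1):(ti * n)
      nu <- rnorm(n, 0, params$sigma_nu)
      u <- if (params$rho != 0) as.numeric(Matrix::solve(B, nu)) else nu
      v <- X[idx, , drop = FALSE] %*% beta + alpha + u
      y[idx] <- if (params$lambda != 0) as.numeric(Matrix::solve(A, v)) else as.numeric(v)
    }
    true_coefs <- NULL
  } else {
    surf <- params$coefficient_surface
    if (is.null(surf)) surf <- default_coefficient_surface(geometry, years)
    probe <- surf(geometry$x[1], geometry$y[1], years[1])
    regs <- setdiff(names(probe), "(Intercept)")
    miss <- setdiff(regs, names(cov_df))
    if (length(miss)) stop("surface regressors missing from covariates: ",
                           paste(miss, collapse = ", "))
    y <- numeric(n * T)
    true_coefs <- matrix(0, n * T, length(probe),
                         dimnames = list(NULL, names(probe)))
    for (ti in seq_len(T)) for (i in seq_len(n)) {
      r <- (ti - 1) * n + i
      b <- surf(geometry$x[i], geometry$y[i], years[ti])
      true_coefs[r, ] <- b
      y[r] <- b[["(Intercept)"]] +
        sum(b[regs] * as.numeric(cov_df[r, regs])) +
        rnorm(1, 0, params$sigma_nu)
    }
    alpha <- NULL
  }

  if (any(y < 0)) {
    warning(sum(y < 0), " negative PM2.5 draws clipped to 0")
    y[y < 0] <- 0
  }
  panel <- data.frame(
    county_id = rep(geometry$county_id, T),
    year = rep(years, each = n),
    pm25 = y,
    x = rep(geometry$x, T), y_coord = rep(geometry$y, T)
  )
  names(panel)[names(panel) == "y_coord"] <- "y"
  cov_cols <- setdiff(names(cov_df), c("county_id", "year"))
  panel[cov_cols] <- cov_df[cov_cols]
  class(panel) <- c("county_panel", "data.frame")
  attr(panel, "covariate_names") <- cov_cols
  if (!is.null(true_coefs)) {
    attr(panel, "true_coefficients") <-
      cbind(panel[c("county_id", "year")], as.data.frame(true_coefs))
  }
  if (params$mode == "constant-coefficients")
    attr(panel, "fixed_effects") <- setNames(alpha, geometry$county_id)
  panel
}

#' Validate a county panel
#'
#' Checks the structural invariants of a long-format balanced county-year
#' panel: every county present in every year, nonnegative PM2.5 and CO2, and
#' percentage columns (names ending `_pct` plus relative humidity) within
#' `[0, 100]`.
#'
#' @param panel a data frame with at least `county_id`, `year`, `pm25`.
#' @return invisibly `TRUE`; errors describe every violated invariant.
#' @export
validate_panel <- function(panel) {
  req <- c("county_id", "year", "pm25")
  miss <- setdiff(req, names(panel))
  if (length(miss)) stop("panel is missing required columns: ",
                         paste(miss, collapse = ", "))
  tab <- table(panel$county_id, panel$year)
  if (any(tab != 1L)) {
    gaps <- which(tab == 0L, arr.ind = TRUE)
    gap_txt <- if (nrow(gaps)) paste(rownames(tab)[gaps[, 1]],
                                     colnames(tab)[gaps[, 2]],
                                     sep = ":", collapse = ", ")
               else "duplicated county-years"
    stop("unbalanced panel; missing county-years: ", gap_txt)
  }
  if (any(panel$pm25 < 0)) stop("pm25 must be nonnegative")
  if ("co2_per_km2" %in% names(panel) && any(panel$co2_per_km2 < 0))
    stop("co2_per_km2 must be nonnegative")
  pct_cols <- c(grep("_pct$", names(panel), value = TRUE),
                intersect(c("rh_summer", "rh_winter"), names(panel)))
  for (cc in pct_cols)
    if (any(panel[[cc]] < 0 | panel[[cc]] > 100))
      stop("percentage column out of [0, 100]: ", cc)
  invisible(TRUE)
}

#' Linear interpolation of sparse yearly series
#'
#' Fills target years by piecewise-linear interpolation between anchor years,
#' the standard treatment for covariates published only in selected vintages.
#' Anchor years are reproduced exactly; targets outside the anchor range take
#' the nearest anchor's value (constant extrapolation), which cannot produce
#' negative percentages.
#'
#' @param anchors data frame with columns `year` and `value` (>= 2 rows, or 1
#'   row if every target coincides with it).
#' @param target_years integer vector of years to fill.
#' @return data frame with columns `year` and `value` for every target year.
#' @export
interpolate_missing_years <- function(anchors, target_years) {
  if (!all(c("year", "value") %in% names(anchors)))
    stop("anchors must have columns year and value")
  anchors <- anchors[order(anchors$year), ]
  if (anyDuplicated(anchors$year)) stop("duplicate anchor years")
  if (nrow(anchors) < 2) {
    if (all(target_years %in% anchors$year))
      return(data.frame(year = target_years,
                        value = rep(anchors$value, length(target_years))))
    stop("need at least 2 anchors to fill years away from the anchors")
  }
  out <- approx(anchors$year, anchors$value, xout = target_years, rule = 2)
  data.frame(year = target_years, value = out$y)
}

#' Simulate baseline PM2.5-attributable mortality for an anchor year
#'
#' Draws each county's anchor-year premature deaths from a Poisson
#' distribution whose means are proportional to county population density
#' (uniform when absent) and scaled so the expected national total equals
#' `total_deaths`. Only the anchor year is filled; the remaining years are
#' produced later by [propagate_mortality()].
#'
#' @param panel a `county_panel`.
#' @param anchor_year year within the panel's range.
#' @param total_deaths expected national total at the anchor year; the default
#'   54730 matches the scale of published national estimates of
#'   PM2.5-attributable premature deaths.
#' @param seed integer seed.
#' @return a `mortality_panel` data frame: `county_id`, `year`, `map_deaths`.
#' @export
simulate_baseline_mortality <- function(panel, anchor_year, total_deaths = 54730,
                                        seed = NULL) {
  if (!anchor_year %in% panel$year)
    stop("anchor_year ", anchor_year, " is outside the panel's year range")
  if (!is.null(seed)) set.seed(seed)
  anchor <- panel[panel$year == anchor_year, ]
  share <- if ("pop_density" %in% names(anchor) && sum(anchor$pop_density) > 0)
    anchor$pop_density / sum(anchor$pop_density)
  else rep(1 / nrow(anchor), nrow(anchor))
  mp <- data.frame(county_id = anchor$county_id, year = anchor_year,
                   map_deaths = rpois(nrow(anchor), total_deaths * share))
  class(mp) <- c("mortality_panel", "data.frame")
  mp
}
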