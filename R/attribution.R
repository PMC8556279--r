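#' Conversion constants between CO2 mass and passenger-vehicle mileage
#'
#' The average passenger vehicle emits about 404 g of CO2 per mile, and one
#' mile is 1.61 km; both constants are overridable.
#'
#' @param grams_co2_per_mile grams of CO2 emitted per vehicle-mile (> 0).
#' @param km_per_mile kilometres per mile (> 0).
#' @return list of class `conversion_constants`.
#' @export
conversion_constants <- function(grams_co2_per_mile = 404, km_per_mile = 1.61) {
  if (grams_co2_per_mile <= 0 || km_per_mile <= 0)
    stop("conversion constants must be strictly positive")
  structure(list(grams_co2_per_mile = grams_co2_per_mile,
                 km_per_mile = km_per_mile),
            class = "conversion_constants")
}

#' Convert a CO2 mass to passenger-vehicle kilometres
#'
#' `km = mass_in_grams / grams_per_mile * km_per_mile`; one million tons of
#' on-road CO2 corresponds to roughly 3.99 billion vehicle-km.
#'
#' @param mass_tons nonnegative CO2 mass in (metric) tons.
#' @param constants a [conversion_constants()].
#' @return vehicle-kilometres.
#' @export
co2_to_mileage <- function(mass_tons, constants = conversion_constants()) {
  if (any(mass_tons < 0)) stop("CO2 mass must be nonnegative")
  mass_tons * 1e6 / constants$grams_co2_per_mile * constants$km_per_mile
}

#' Mileage increase associated with a unit PM2.5 increase
#'
#' Inverts a (total-impact) coefficient `beta_total`, expressed in micrograms
#' per cubic metre of PM2.5 per 1e6 t/km2 of on-road CO2, into the billion
#' vehicle-km per km2 associated with a 1 microgram per cubic metre PM2.5
#' increase. The mileage factor is computed exactly from the constants
#' (about 3.985 Gkm per Mt) and never pre-rounded.
#'
#' @param beta_total positive coefficient.
#' @param constants a [conversion_constants()].
#' @return billion vehicle-km per km2 per microgram per cubic metre.
#' @export
mileage_per_unit_pm25 <- function(beta_total, constants = conversion_constants()) {
  if (any(beta_total <= 0))
    stop("beta_total must be positive (association direction undefined otherwise)")
  co2_to_mileage(1e6, constants) / 1e9 / beta_total
}

#' Contribution of on-road transportation to PM2.5 concentration
#'
#' Per county-year, `con_raw = beta_it * CO2_it / concentration_it * 100`,
#' where `beta_it` is the local GTWR coefficient of on-road CO2 density
#' (micrograms per cubic metre per 1e6 t/km2), `CO2_it` the CO2 density and
#' `concentration_it` the PM2.5 level. The raw share may leave `[0, 100]`
#' because of the other covariates and residuals; [clamp_contribution()]
#' restricts it. `co2_averaging = "period-mean"` substitutes each county's
#' study-period mean CO2 density for the yearly value.
#'
#' @param gtwr_fit a `gtwr_fit` whose local coefficients include `co2_col`.
#' @param panel the `county_panel` the fit was computed on (aligned on
#'   county-year).
#' @param co2_col name of the CO2 density column/coefficient.
#' @param co2_averaging `"yearly"` (default) or `"period-mean"`.
#' @return data frame of class `contribution_surface`: `county_id`, `year`,
#'   `beta_co2`, `co2`, `concentration`, `con_raw`, `con_clamped`.
#' @export
contribution <- function(gtwr_fit, panel, co2_col = "co2_per_km2",
                         co2_averaging = c("yearly", "period-mean")) {
  co2_averaging <- match.arg(co2_averaging)
  stopifnot(inherits(gtwr_fit, "gtwr_fit"))
  if (!co2_col %in% names(gtwr_fit$local))
    stop("GTWR fit has no local coefficient for ", co2_col)
  key_fit <- paste(gtwr_fit$local$county_id, gtwr_fit$local$year)
  key_pan <- paste(panel$county_id, panel$year)
  idx <- match(key_fit, key_pan)
  if (anyNA(idx)) stop("panel and GTWR fit are not aligned on county-year")
  conc <- panel$pm25[idx]
  if (any(conc <= 0)) {
    bad <- key_fit[which(conc <= 0)[1]]
    stop("non-positive PM2.5 concentration at county-year ", bad)
  }
  co2 <- panel[[co2_col]][idx]
  if (co2_averaging == "period-mean") {
    mu <- tapply(panel[[co2_col]], panel$county_id, mean)
    co2 <- as.numeric(mu[as.character(gtwr_fit$local$county_id)])
  }
  beta <- gtwr_fit$local[[co2_col]]
  con_raw <- beta * co2 / conc * 100
  out <- data.frame(county_id = gtwr_fit$local$county_id,
                    year = gtwr_fit$local$year,
                    beta_co2 = beta, co2 = co2, concentration = conc,
                    con_raw = con_raw,
                    con_clamped = pmin(pmax(con_raw, 0), 100))
  class(out) <- c("contribution_surface", "data.frame")
  out
}

#' Clamp contribution shares to [0, 100] percent
#'
#' Shares below 0 are set to 0 (on-road emissions cannot clean the air) and
#' shares above 100 to 100; values already inside the band are unchanged, so
#' the operation is idempotent.
#'
#' @param surface a `contribution_surface` (or any data frame with
#'   `con_raw`).
#' @return the surface with `con_clamped` filled.
#' @export
clamp_contribution <- function(surface) {
  if (!"con_raw" %in% names(surface)) stop("surface must carry con_raw")
  surface$con_clamped <- pmin(pmax(surface$con_raw, 0), 100)
  surface
}

#' Propagate baseline mortality across years
#'
#' From an anchor-year baseline of PM2.5-attributable premature deaths, fills
#' the remaining panel years with the recursion
#' `MAP_t = MAP_{t-1} * (1 + CPD * (AP_t - AP_{t-1}))`, where `AP` is the
#' county's annual mean PM2.5 and `CPD` the concentration-mortality
#' coefficient (fractional change in deaths per microgram per cubic metre;
#' default 0.012). Years before the anchor use the exact algebraic inverse,
#' so a forward-then-backward round trip reproduces the anchor. Negative
#' intermediate values are clipped to 0 with a warning; a concentration jump
#' making `1 + CPD * dAP <= 0` is an error.
#'
#' @param baseline `mortality_panel` holding the anchor year for every
#'   county.
#' @param panel a `county_panel` with `pm25` for all county-years.
#' @param cpd concentration-mortality coefficient per microgram per cubic
#'   metre.
#' @return a `mortality_panel` covering every county-year of `panel`.
#' @export
propagate_mortality <- function(baseline, panel, cpd = 0.012) {
  anchor_year <- unique(baseline$year)
  if (length(anchor_year) != 1L)
    stop("baseline must contain exactly one anchor year")
  years <- sort(unique(panel$year))
  if (!anchor_year %in% years) stop("anchor year absent from the panel")
  ids <- unique(panel$county_id)
  if (!all(ids %in% baseline$county_id))
    stop("baseline is missing counties present in the panel")

  pm <- matrix(NA_real_, length(ids), length(years),
               dimnames = list(ids, years))
  pm[cbind(match(panel$county_id, ids), match(panel$year, years))] <- panel$pm25
  if (anyNA(pm)) stop("pm25 missing for some county-years")

  map <- matrix(NA_real_, length(ids), length(years),
                dimnames = list(ids, years))
  a <- match(anchor_year, years)
  map[match(baseline$county_id, ids), a] <- baseline$map_deaths
  growth <- 1 + cpd * (pm[, -1, drop = FALSE] - pm[, -ncol(pm), drop = FALSE])
  if (any(growth <= 0))
    stop("degenerate concentration jump: 1 + CPD * dAP <= 0 at some step")
  if (a < length(years))
    for (j in (a + 1):length(years)) map[, j] <- map[, j - 1] * growth[, j - 1]
  if (a > 1)
    for (j in (a - 1):1) map[, j] <- map[, j + 1] / growth[, j]
  if (any(map < 0)) {
    warning(sum(map < 0), " negative propagated death counts clipped to 0")
    map[map < 0] <- 0
  }
  out <- data.frame(county_id = rep(ids, length(years)),
                    year = rep(years, each = length(ids)),
                    map_deaths = as.numeric(map))
  class(out) <- c("mortality_panel", "data.frame")
  out
}

#' Percentage of deaths attributable to on-road transportation
#'
#' `pta(mapor, map) = sum(mapor) / sum(map) * 100`: the pooled ratio of
#' attributable to total deaths, not the mean of yearly percentages.
#'
#' @param mapor deaths attributable to on-road transportation.
#' @param map total PM2.5-attributable deaths.
#' @return percentage in `[0, 100]`.
#' @export
pta <- function(mapor, map) {
  if (sum(map) <= 0) stop("total deaths must be positive")
  sum(mapor) / sum(map) * 100
}

#' Attribute premature deaths to on-road transportation
#'
#' Per county-year, `MAPOR = MAP * C / 100` with `C` the clamped contribution
#' share; yearly national totals and yearly and pooled attribution
#' percentages follow. The clamp guarantees `0 <= MAPOR <= MAP` everywhere.
#'
#' @param mortality a `mortality_panel` (see [propagate_mortality()]).
#' @param surface a clamped `contribution_surface`.
#' @return list of class `attribution_result`: `county` (county-year MAP and
#'   MAPOR), `yearly` (year, map_total, mapor_total, pta_pct), and
#'   `pta_pooled`.
#' @export
attributable_deaths <- function(mortality, surface) {
  if (!"con_clamped" %in% names(surface) || anyNA(surface$con_clamped))
    stop("surface must be clamped first (see clamp_contribution())")
  key_m <- paste(mortality$county_id, mortality$year)
  key_s <- paste(surface$county_id, surface$year)
  idx <- match(key_s, key_m)
  if (anyNA(idx)) stop("mortality panel and contribution surface are misaligned")
  county <- data.frame(county_id = surface$county_id, year = surface$year,
                       map_deaths = mortality$map_deaths[idx],
                       con_clamped = surface$con_clamped)
  county$mapor_deaths <- county$map_deaths * county$con_clamped / 100
  stopifnot(all(county$mapor_deaths <= county$map_deaths + 1e-12),
            all(county$mapor_deaths >= 0))
  yearly <- do.call(rbind, lapply(split(county, county$year), function(g) {
    data.frame(year = g$year[1], map_total = sum(g$map_deaths),
               mapor_total = sum(g$mapor_deaths),
               pta_pct = pta(g$mapor_deaths, g$map_deaths))
  }))
  rownames(yearly) <- NULL
  out <- list(county = county, yearly = yearly,
              pta_pooled = pta(county$mapor_deaths, county$map_deaths))
  class(out) <- "attribution_result"
  out
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("Attribution over %d county-years (%d years): pooled PTA = %.2f%%\n",
              nrow(x$county), nrow(x$yearly), x$pta_pooled))
  print(transform(x$yearly,
                  map_total = round(map_total), mapor_total = round(mapor_total),
                  pta_pct = round(pta_pct, 2)), row.names = FALSE)
  invisible(x)
}

#' Serialize an attribution result
#'
#' Writes the county-year table and the yearly national summary (year, total
#' deaths, on-road deaths, percentage) as two CSV files. Deaths are kept as
#' reals internally and rounded only in this display-oriented output.
#'
#' @param result an `attribution_result`.
#' @param county_path,yearly_path output CSV paths.
#' @export
write_attribution <- function(result, county_path, yearly_path) {
  write.csv(result$county, county_path, row.names = FALSE)
  yr <- result$yearly
  yr$map_total <- round(yr$map_total)
  yr$mapor_total <- round(yr$mapor_total)
  yr$pta_pct <- round(yr$pta_pct, 2)
  write.csv(yr, yearly_path, row.names = FALSE)
  invisible(yearly_path)
}
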