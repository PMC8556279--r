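#' Model specification for the panel regressions
#'
#' @param dependent name of the outcome column (annual mean PM2.5).
#' @param regressors ordered character vector of regressor columns. No
#'   constant term is included: the county fixed effects absorb it.
#' @return a `model_spec` list.
#' @export
model_spec <- function(dependent = "pm25",
                       regressors = c("co2_per_km2", "dev_open_pct",
                                      "dev_low_pct", "dev_med_pct",
                                      "forest_pct", "grass_pct",
                                      "pop_density", "temp_summer",
                                      "temp_winter", "rh_summer",
                                      "rh_winter")) {
  stopifnot(is.character(dependent), length(dependent) == 1L,
            is.character(regressors), length(regressors) >= 1L)
  structure(list(dependent = dependent, regressors = regressors),
            class = "model_spec")
}

# Shared plumbing: sorts the panel year-major, checks balance, extracts y and
# X, and computes the within (county-demeaned) transforms used by every panel
# estimator.
panel_design <- function(panel, spec) {
  miss <- setdiff(c(spec$dependent, spec$regressors), names(panel))
  if (length(miss)) stop("panel is missing model columns: ",
                         paste(miss, collapse = ", "))
  panel <- panel[order(panel$year, panel$county_id), ]
  ids <- unique(panel$county_id)
  years <- unique(panel$year)
  n <- length(ids); T <- length(years)
  if (nrow(panel) != n * T ||
      !all(table(panel$county_id, panel$year) == 1L))
    stop("balanced panel required (every county in every year)")
  if (T < 2) stop("at least 2 time periods are required")
  y <- panel[[spec$dependent]]
  X <- as.matrix(panel[spec$regressors])
  id_f <- factor(panel$county_id, levels = ids)
  demean <- function(v) v - ave(v, id_f)
  yw <- demean(y)
  Xw <- apply(X, 2, demean)
  list(panel = panel, ids = ids, years = years, n = n, T = T,
       y = y, X = X, yw = yw, Xw = Xw, id_f = id_f)
}

#' Fixed-effects (within) estimator
#'
#' Ordinary least squares after demeaning outcome and regressors within each
#' county, removing the unobserved time-invariant county effects. Fixed
#' effects are recovered as county means of the partial residuals; the
#' reported R-squared is the within R-squared, `1 - SSR/SST` on the demeaned
#' data.
#'
#' @param panel a balanced `county_panel`.
#' @param spec a [model_spec()].
#' @return object of class `fem_fit` with `coefficients` (estimate, std.
#'   error, 95% CI), `fixed_effects`, within `residuals`, `r_squared`,
#'   `n_obs`, `df`, and the demeaned design kept for the spatial diagnostics.
#' @export
fit_fem <- function(panel, spec = model_spec()) {
  d <- panel_design(panel, spec)
  qx <- qr(d$Xw)
  if (qx$rank < ncol(d$Xw)) {
    bad <- colnames(d$Xw)[qx$pivot[(qx$rank + 1):ncol(d$Xw)]]
    stop("rank-deficient design after within-transformation; collinear ",
         "columns: ", paste(bad, collapse = ", "))
  }
  b <- qr.coef(qx, d$yw)
  res <- d$yw - d$Xw %*% b
  ssr <- sum(res^2)
  df <- d$n * d$T - d$n - ncol(d$Xw)
  sigma2 <- ssr / df
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * diag(xtx_inv))
  tc <- qt(0.975, df)
  coefs <- data.frame(term = colnames(d$Xw), estimate = as.numeric(b),
                      std_error = se,
                      ci_lower = as.numeric(b) - tc * se,
                      ci_upper = as.numeric(b) + tc * se,
                      row.names = NULL)
  alpha <- tapply(d$y - d$X %*% b, d$id_f, mean)
  fit <- list(coefficients = coefs,
              fixed_effects = setNames(as.numeric(alpha), d$ids),
              residuals = as.numeric(res),
              r_squared = 1 - ssr / sum(d$yw^2),
              sigma2 = sigma2, n_obs = d$n * d$T, df = df,
              design = d, spec = spec)
  class(fit) <- "fem_fit"
  fit
}

#' @export
print.fem_fit <- function(x, ...) {
  cat(sprintf("Fixed-effects panel model: %d counties x %d years, within R2 = %.3f\n",
              x$design$n, x$design$T, x$r_squared))
  m <- as.matrix(x$coefficients[, c("estimate", "std_error")])
  rownames(m) <- x$coefficients$term
  printCoefmat(m, ...)
  invisible(x)
}

#' Panel specification tests: pooling, random effects, Hausman
#'
#' Runs the classical balanced-panel battery guiding the choice between
#' pooled OLS, random effects, and fixed effects:
#' * F test for individual effects (pooled OLS vs fixed effects),
#' * Breusch-Pagan Lagrange multiplier test (pooled OLS vs random effects),
#' * Hausman test (random vs fixed effects, Swamy-Arora GLS for the RE side).
#'
#' @param panel a balanced `county_panel`.
#' @param spec a [model_spec()].
#' @return list of class `panel_diagnostics` with elements `f_individual`,
#'   `bp_lm`, `hausman`, each carrying `statistic`, `df`, `p_value`.
#' @export
panel_diagnostics <- function(panel, spec = model_spec()) {
  d <- panel_design(panel, spec)
  n <- d$n; T <- d$T; K <- ncol(d$Xw)

  # pooled OLS with intercept
  Xp <- cbind("(Intercept)" = 1, d$X)
  fp <- lm.fit(Xp, d$y)
  ep <- fp$residuals
  ssr_p <- sum(ep^2)

  # within fit
  bw <- qr.coef(qr(d$Xw), d$yw)
  ew <- d$yw - d$Xw %*% bw
  ssr_w <- sum(ew^2)
  df2 <- n * T - n - K
  f_stat <- ((ssr_p - ssr_w) / (n - 1)) / (ssr_w / df2)
  f_p <- pf(f_stat, n - 1, df2, lower.tail = FALSE)

  # Breusch-Pagan LM for random effects
  sum_i <- tapply(ep, d$id_f, sum)
  lm_stat <- (n * T) / (2 * (T - 1)) * (sum(sum_i^2) / sum(ep^2) - 1)^2
  lm_p <- pchisq(lm_stat, df = 1, lower.tail = FALSE)

  # Swamy-Arora random effects and Hausman
  sigma2_nu <- ssr_w / (n * (T - 1) - K)
  ybar <- tapply(d$y, d$id_f, mean)
  Xbar <- apply(d$X, 2, function(v) tapply(v, d$id_f, mean))
  fb <- lm.fit(cbind(1, Xbar), as.numeric(ybar))
  sigma2_1 <- sum(fb$residuals^2) / max(n - K - 1, 1)
  sigma2_alpha <- max(sigma2_1 - sigma2_nu / T, 0)
  theta <- 1 - sqrt(sigma2_nu / (sigma2_nu + T * sigma2_alpha))
  yq <- as.numeric(d$y - theta * ybar[d$id_f])
  Xq <- cbind("(Intercept)" = 1 - theta,
              d$X - Xbar[d$id_f, , drop = FALSE] * theta)
  qre <- qr(Xq)
  bre <- qr.coef(qre, yq)
  ere <- yq - Xq %*% bre
  s2re <- sum(ere^2) / (n * T - K - 1)
  Vre <- s2re * chol2inv(qr.R(qre))
  # FEM side
  xtx_inv <- chol2inv(qr.R(qr(d$Xw)))
  Vfe <- (ssr_w / df2) * xtx_inv
  q <- as.numeric(bw) - as.numeric(bre[-1])
  Vd <- Vfe - Vre[-1, -1, drop = FALSE]
  h_stat <- tryCatch(as.numeric(t(q) %*% solve(Vd, q)),
                     error = function(e) as.numeric(t(q) %*% MASS::ginv(Vd) %*% q))
  if (!is.finite(h_stat) || h_stat < 0)
    h_stat <- as.numeric(t(q) %*% MASS::ginv(Vd) %*% q)
  h_stat <- abs(h_stat)
  h_p <- pchisq(h_stat, df = K, lower.tail = FALSE)

  out <- list(
    f_individual = list(statistic = f_stat, df = c(n - 1, df2), p_value = f_p),
    bp_lm = list(statistic = lm_stat, df = 1, p_value = lm_p),
    hausman = list(statistic = h_stat, df = K, p_value = h_p)
  )
  class(out) <- "panel_diagnostics"
  out
}

#' @export
print.panel_diagnostics <- function(x, ...) {
  fmt <- function(name, t) cat(sprintf("  %-22s stat = %10.3f  p = %.4g\n",
                                       name, t$statistic, t$p_value))
  cat("Panel specification tests:\n")
  fmt("F (individual effects)", x$f_individual)
  fmt("Breusch-Pagan LM", x$bp_lm)
  fmt("Hausman", x$hausman)
  if (!is.null(x$robust_lm_lag)) fmt("robust LM lag", x$robust_lm_lag)
  if (!is.null(x$robust_lm_error)) fmt("robust LM error", x$robust_lm_error)
  invisible(x)
}

#' Locally robust Lagrange multiplier tests for spatial dependence
#'
#' Computes the locally robust LM tests for a spatially lagged dependent
#' variable and for spatial error correlation, each robust to local presence
#' of the other alternative, on the pooled within-transformed panel (the
#' fixed-effects analogue of the classical cross-section pair). Both
#' statistics are asymptotically chi-squared with 1 degree of freedom under
#' their nulls. The error variance uses the demeaning-aware denominator
#' `N(T-1)` and the kernel trace scales with `T-1`, which calibrates the null
#' size under the within transformation.
#'
#' @param fem_fit a fitted [fit_fem()] object.
#' @param w row-standardized `sp_weights` whose `ids` match the panel's
#'   counties.
#' @return list of class `panel_diagnostics` with `robust_lm_lag` and
#'   `robust_lm_error`.
#' @export
robust_lm_tests <- function(fem_fit, w) {
  stopifnot(inherits(fem_fit, "fem_fit"), inherits(w, "sp_weights"))
  d <- fem_fit$design
  if (!identical(as.character(d$ids), w$ids))
    stop("panel counties and weights ids do not match (same units, same order required)")
  n <- d$n; T <- d$T
  W <- weights_matrix(w)
  e <- fem_fit$residuals
  sigma2 <- sum(e^2) / (n * (T - 1))

  lag_blocks <- function(v) {      # apply W year by year to a stacked vector
    out <- numeric(length(v))
    for (ti in seq_len(T)) {
      idx <- ((ti - 1) * n + 1):(ti * n)
      out[idx] <- as.numeric(W %*% v[idx])
    }
    out
  }
  Wy <- lag_blocks(d$yw)
  We <- lag_blocks(e)
  b <- fem_fit$coefficients$estimate
  WXb <- lag_blocks(as.numeric(d$Xw %*% b))
  # projection of WXb off the within design
  qx <- qr(d$Xw)
  MWXb <- WXb - d$Xw %*% qr.coef(qx, WXb)

  d_y <- sum(e * Wy) / sigma2
  d_e <- sum(e * We) / sigma2
  Wm <- weights_matrix(w)
  trw <- sum(Matrix::t(Wm) * Wm) + sum(Wm * Wm)   # tr(W'W) + tr(WW)
  Tw <- (T - 1) * trw
  D <- sum(WXb * MWXb) / sigma2 + Tw

  rlm_lag <- (d_y - d_e)^2 / (D - Tw)
  rlm_err <- (d_e - (Tw / D) * d_y)^2 / (Tw * (1 - Tw / D))
  out <- list(
    robust_lm_lag = list(statistic = rlm_lag, df = 1,
                         p_value = pchisq(rlm_lag, 1, lower.tail = FALSE)),
    robust_lm_error = list(statistic = rlm_err, df = 1,
                           p_value = pchisq(rlm_err, 1, lower.tail = FALSE))
  )
  class(out) <- "panel_diagnostics"
  out
}

#' Model recommendation from the diagnostic battery
#'
#' Applies the decision tree used for model selection: significant F, BP-LM
#' and Hausman tests favour fixed effects over pooled OLS and random effects;
#' significant robust LM lag and/or error tests then upgrade the fixed-effects
#' model to its spatial lag, spatial error, or combined (Durbin-type
#' lag-plus-error) counterpart. When both robust LM tests reject, the combined
#' model is recommended.
#'
#' @param diagnostics output of [panel_diagnostics()].
#' @param rlm output of [robust_lm_tests()] (optional).
#' @param alpha significance level of the tree (default 0.001, i.e. 0.1%).
#' @return character scalar: one of `"OLS"`, `"REM"`, `"FEM"`, `"SPAM"`,
#'   `"SPEM"`, `"SPDM"`.
#' @export
recommend_model <- function(diagnostics, rlm = NULL, alpha = 0.001) {
  sig <- function(t) !is.null(t) && is.finite(t$p_value) && t$p_value < alpha
  if (!sig(diagnostics$f_individual) && !sig(diagnostics$bp_lm)) return("OLS")
  base <- if (!sig(diagnostics$hausman) && sig(diagnostics$bp_lm)) "REM" else "FEM"
  if (is.null(rlm)) return(base)
  lag_sig <- sig(rlm$robust_lm_lag)
  err_sig <- sig(rlm$robust_lm_error)
  if (lag_sig && err_sig) "SPDM"
  else if (lag_sig) "SPAM"
  else if (err_sig) "SPEM"
  else base
}
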