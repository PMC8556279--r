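#' Maximum-likelihood spatial panel models with fixed effects
#'
#' Fits, on the within-transformed (county-demeaned) panel, one of
#' * `variant = "lag"`: spatially lagged dependent variable,
#'   `y = lambda W y + X beta + alpha + nu`;
#' * `variant = "error"`: spatially autocorrelated error,
#'   `y = X beta + alpha + u`, `u = rho W u + nu`;
#' * `variant = "sac"`: both simultaneously (the combined lag-error model the
#'   Durbin-type specification reduces to when no lagged regressors are
#'   added).
#'
#' Estimation concentrates the Gaussian log-likelihood over the spatial
#' parameters: given `(lambda, rho)` the slope vector is generalized least
#' squares on the doubly filtered data, and the log-determinants
#' `log|I - lambda W|`, `log|I - rho W|` come from the (real) eigenvalues of
#' the row-standardized weights matrix, computed once. The demeaned
#' likelihood uses `T - 1` effective periods per county, the degrees of
#' freedom left by the fixed effects. The spatial parameters are constrained
#' to the stationarity interval given by the extreme eigenvalues of `W`;
#' for `"sac"` the optimizer restarts from `(0, 0)` and the `(+-0.5, +-0.5)`
#' grid and keeps the best likelihood, ties broken by smaller
#' `|lambda| + |rho|`.
#'
#' @param panel a balanced `county_panel`.
#' @param w row-standardized `sp_weights` matching the panel's counties.
#' @param spec a [model_spec()].
#' @param variant `"lag"`, `"error"`, or `"sac"`.
#' @param tol convergence tolerance on the concentrated log-likelihood.
#' @return object of class `spatial_panel_fit`: `coefficients` (estimate,
#'   std. error, 95% CI), `lambda`, `rho` (NA when absent from the variant),
#'   `log_likelihood`, `fixed_effects`, residual components `eps`
#'   (spatially related) and `nu` (idiosyncratic), `r_squared` (squared
#'   correlation of reduced-form fitted values with observations), and a
#'   `convergence` record.
#' @export
fit_spatial_panel <- function(panel, w, spec = model_spec(),
                              variant = c("lag", "error", "sac"),
                              tol = 1e-8) {
  variant <- match.arg(variant)
  stopifnot(inherits(w, "sp_weights"))
  if (!w$standardized)
    stop("row-standardized weights required (see row_standardize())")
  d <- panel_design(panel, spec)
  if (!identical(as.character(d$ids), w$ids))
    stop("panel counties and weights ids do not match")
  n <- d$n; T <- d$T; K <- ncol(d$Xw)
  W <- weights_matrix(w)
  ev <- weights_eigenvalues(w)
  lo <- 1 / min(ev) + 1e-6
  hi <- 1 / max(ev) - 1e-6
  Teff <- T - 1

  lag_blocks <- function(v) {
    out <- numeric(length(v))
    for (ti in seq_len(T)) {
      idx <- ((ti - 1) * n + 1):(ti * n)
      out[idx] <- as.numeric(W %*% v[idx])
    }
    out
  }
  yw <- d$yw; Xw <- d$Xw
  Wy <- lag_blocks(yw)
  WX <- apply(Xw, 2, lag_blocks)
  WWy <- lag_blocks(Wy)

  # concentrated profile: beta and sigma2 given (lambda, rho)
  profile <- function(lambda, rho) {
    # z = B(Ay) with A = I - lambda W, B = I - rho W, applied per year
    zy <- yw - lambda * Wy - rho * Wy + lambda * rho * WWy
    zx <- if (rho != 0) Xw - rho * WX else Xw
    fit <- lm.fit(zx, zy)
    ssr <- sum(fit$residuals^2)
    list(beta = coef(fit), ssr = ssr, zx = zx, resid = fit$residuals)
  }
  logdet <- function(param) sum(log(1 - param * ev))
  nll <- function(par) {
    lambda <- if (variant %in% c("lag", "sac")) par[["lambda"]] else 0
    rho <- if (variant %in% c("error", "sac")) par[["rho"]] else 0
    p <- profile(lambda, rho)
    sigma2 <- p$ssr / (n * Teff)
    0.5 * n * Teff * log(sigma2) -
      Teff * ((if (lambda != 0) logdet(lambda) else 0) +
              (if (rho != 0) logdet(rho) else 0))
  }

  convergence <- list(boundary = FALSE, restarts = NA_integer_)
  if (variant == "sac") {
    starts <- list(c(0, 0), c(0.5, 0.5), c(0.5, -0.5), c(-0.5, 0.5), c(-0.5, -0.5))
    best <- NULL
    for (s in starts) {
      o <- tryCatch(
        optim(setNames(pmin(pmax(s, lo + 0.01), hi - 0.01), c("lambda", "rho")),
              nll, method = "L-BFGS-B",
              lower = c(lo, lo), upper = c(hi, hi),
              control = list(factr = tol / .Machine$double.eps)),
        error = function(e) NULL)
      if (is.null(o)) next
      if (is.null(best) || o$value < best$value - 1e-10 ||
          (abs(o$value - best$value) <= 1e-10 &&
           sum(abs(o$par)) < sum(abs(best$par))))
        best <- o
    }
    if (is.null(best)) stop("spatial ML optimizer failed to converge from all starts")
    lambda <- best$par[["lambda"]]; rho <- best$par[["rho"]]
    convergence$restarts <- length(starts)
    nll_min <- best$value
  } else {
    o <- optimize(function(p) nll(setNames(p, if (variant == "lag") "lambda" else "rho")),
                  interval = c(lo, hi), tol = 1e-9)
    if (variant == "lag") { lambda <- o$minimum; rho <- 0 }
    else { lambda <- 0; rho <- o$minimum }
    nll_min <- o$objective
  }
  if (min(hi - max(abs(c(lambda, rho))), 1) < 1e-4 ||
      lambda < lo + 1e-4 || rho < lo + 1e-4) {
    convergence$boundary <- TRUE
    warning("spatial parameter estimate at the stationarity boundary")
  }

  p <- profile(lambda, rho)
  sigma2 <- p$ssr / (n * Teff)
  log_lik <- -0.5 * n * Teff * (log(2 * pi) + 1) - nll_min
  xtx_inv <- chol2inv(qr.R(qr(p$zx)))
  se <- sqrt(sigma2 * diag(xtx_inv))
  zc <- qnorm(0.975)
  beta <- as.numeric(p$beta)
  coefs <- data.frame(term = colnames(Xw), estimate = beta, std_error = se,
                      ci_lower = beta - zc * se, ci_upper = beta + zc * se,
                      row.names = NULL)

  # residual components on the within scale
  eps <- yw - lambda * Wy - Xw %*% beta          # spatially related error
  nu <- as.numeric(p$resid)                      # idiosyncratic
  # fixed effects and reduced-form fitted values on the raw scale
  Ay <- d$y - lambda * lag_blocks(d$y)
  alpha <- tapply(Ay - d$X %*% beta, d$id_f, mean)
  fitted <- numeric(n * T)
  A <- Matrix::Diagonal(n) - lambda * W
  for (ti in seq_len(T)) {
    idx <- ((ti - 1) * n + 1):(ti * n)
    v <- d$X[idx, , drop = FALSE] %*% beta + as.numeric(alpha)
    fitted[idx] <- if (lambda != 0) as.numeric(Matrix::solve(A, v)) else as.numeric(v)
  }
  fit <- list(variant = variant, coefficients = coefs,
              lambda = if (variant %in% c("lag", "sac")) lambda else NA_real_,
              rho = if (variant %in% c("error", "sac")) rho else NA_real_,
              sigma2 = sigma2, log_likelihood = log_lik,
              fixed_effects = setNames(as.numeric(alpha), d$ids),
              eps = as.numeric(eps), nu = nu,
              r_squared = suppressWarnings(stats::cor(fitted, d$y)^2),
              n_obs = n * T, convergence = convergence,
              design = d, spec = spec)
  class(fit) <- "spatial_panel_fit"
  fit
}

#' @export
print.spatial_panel_fit <- function(x, ...) {
  cat(sprintf("Spatial panel model (%s): %d counties x %d years\n",
              x$variant, x$design$n, x$design$T))
  if (!is.na(x$lambda)) cat(sprintf("  lambda (spatial lag)   = %8.4f\n", x$lambda))
  if (!is.na(x$rho)) cat(sprintf("  rho    (spatial error) = %8.4f\n", x$rho))
  cat(sprintf("  log-likelihood = %.3f, R2 = %.3f\n", x$log_likelihood, x$r_squared))
  m <- as.matrix(x$coefficients[, c("estimate", "std_error")])
  rownames(m) <- x$coefficients$term
  printCoefmat(m, ...)
  invisible(x)
}

#' Direct, indirect and total impacts of a spatial lag fit
#'
#' With a spatially lagged outcome, a change in a regressor in one county
#' propagates through the spatial multiplier `(I - lambda W)^{-1}`. The
#' multiplier is expanded as the truncated power series
#' `sum_{s=0}^{n_terms} lambda^s W^s` (500 terms by default), and for each
#' regressor `k` the impacts are summarized as: direct = average diagonal
#' element times `beta_k` (own-county effect), total = average row sum times
#' `beta_k`, and indirect = total - direct (the spillover). For
#' row-standardized weights the total converges to `beta_k / (1 - lambda)`.
#'
#' @param fit a `spatial_panel_fit` with a lag component (`"lag"` or
#'   `"sac"`).
#' @param w the `sp_weights` used in the fit.
#' @param n_terms number of series terms (>= 1).
#' @return data frame of class `impact_estimates`: one row per regressor with
#'   `direct`, `indirect`, `total`; attribute `n_terms`.
#' @export
panel_impacts <- function(fit, w, n_terms = 500) {
  stopifnot(inherits(fit, "spatial_panel_fit"))
  if (is.na(fit$lambda))
    stop("impacts require a fit with a spatial lag (variant 'lag' or 'sac')")
  if (n_terms < 1) stop("n_terms must be at least 1")
  lambda <- fit$lambda
  if (abs(lambda) >= 1) stop("|lambda| must be below 1 for the series to converge")
  Wd <- as.matrix(weights_matrix(w))
  n <- nrow(Wd)
  acc <- diag(n)       # s = 0 term
  cur <- diag(n)
  for (s in seq_len(n_terms)) {
    cur <- lambda * (Wd %*% cur)
    acc <- acc + cur
    if (max(abs(cur)) < 1e-16) break
  }
  mean_diag <- mean(diag(acc))
  mean_rowsum <- mean(rowSums(acc))
  beta <- fit$coefficients$estimate
  direct <- mean_diag * beta
  total <- mean_rowsum * beta
  out <- data.frame(term = fit$coefficients$term,
                    direct = direct, indirect = total - direct, total = total,
                    row.names = NULL)
  attr(out, "n_terms") <- n_terms
  class(out) <- c("impact_estimates", "data.frame")
  out
}
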