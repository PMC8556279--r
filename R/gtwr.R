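#' Spatio-temporal kernel parameters
#'
#' The combined squared distance between two county-year observations is
#' `d^2 = phi_s * dS^2 + phi_t * dT^2`, with `dS` the planar Euclidean
#' distance between centroids (km) and `dT` the absolute year difference.
#' Under an adaptive bandwidth only the ratio `tau = phi_t / phi_s` matters
#' (jointly rescaling both factors rescales every distance and the kernel
#' radius alike), so `phi_s` is fixed at 1 and `tau` is searched during
#' bandwidth selection.
#'
#' @param phi_s nonnegative spatial scale factor.
#' @param phi_t nonnegative temporal scale factor.
#' @return list of class `st_kernel_params` with `phi_s`, `phi_t`, `tau`.
#' @export
st_kernel_params <- function(phi_s = 1, phi_t = phi_s) {
  if (phi_s < 0 || phi_t < 0) stop("scale factors must be nonnegative")
  if (phi_s == 0 && phi_t == 0) stop("phi_s and phi_t cannot both be zero")
  structure(list(phi_s = phi_s, phi_t = phi_t,
                 tau = if (phi_s > 0) phi_t / phi_s else Inf),
            class = "st_kernel_params")
}

#' Combined squared spatio-temporal distances
#'
#' @param focal numeric vector `c(x, y, t)` of the focal observation.
#' @param others matrix or data frame with columns `x`, `y`, `t` (or three
#'   unnamed columns in that order).
#' @param params an [st_kernel_params()].
#' @return numeric vector of squared combined distances.
#' @export
st_distances <- function(focal, others, params = st_kernel_params()) {
  stopifnot(inherits(params, "st_kernel_params"))
  m <- as.matrix(others)
  if (!is.null(colnames(m)) && all(c("x", "y", "t") %in% colnames(m)))
    m <- m[, c("x", "y", "t"), drop = FALSE]
  params$phi_s * ((m[, 1] - focal[1])^2 + (m[, 2] - focal[2])^2) +
    params$phi_t * (m[, 3] - focal[3])^2
}

#' Gaussian kernel weights over a subsample
#'
#' Weights decay as `exp(-d^2 / b^2)` for the members of the local subsample
#' and are exactly zero outside it; the member at distance `b` (the k-th
#' neighbour that defines the adaptive radius) receives weight `exp(-1)`.
#'
#' @param d2 squared combined distances (see [st_distances()]).
#' @param b kernel radius (the k-th smallest combined distance), > 0.
#' @param member logical vector flagging subsample membership.
#' @return numeric weight vector, in (0, 1] for members, 0 otherwise.
#' @export
kernel_weights <- function(d2, b, member = rep(TRUE, length(d2))) {
  if (length(b) != 1L || !is.finite(b) || b <= 0)
    stop("kernel radius b must be a positive scalar")
  ifelse(member, exp(-d2 / b^2), 0)
}

# Weighted least squares on the k nearest space-time neighbours of one
# observation. ord must index d2 ascending. Returns the coefficient vector
# (intercept first); falls back to a tiny ridge when the local design is
# singular.
local_wls <- function(X1, yv, d2, ord, k, ridge_counter = NULL, fixed_b2 = NULL) {
  members <- ord[seq_len(k)]
  b2 <- if (!is.null(fixed_b2)) fixed_b2 else d2[members[k]]
  if (b2 <= 0) b2 <- max(d2[members], .Machine$double.eps)
  wts <- exp(-d2[members] / b2)
  Xm <- X1[members, , drop = FALSE]
  ym <- yv[members]
  XtW <- t(Xm * wts)
  A <- XtW %*% Xm
  bvec <- XtW %*% ym
  out <- tryCatch(solve(A, bvec), error = function(e) NULL)
  if (is.null(out)) {
    A <- A + diag(1e-8 * sum(diag(A)), ncol(A))
    out <- solve(A, bvec)
    if (!is.null(ridge_counter)) ridge_counter$n <- ridge_counter$n + 1L
  }
  list(coef = as.numeric(out), wsum = sum(wts))
}

gtwr_design <- function(panel, spec) {
  miss <- setdiff(c(spec$dependent, spec$regressors, "x", "y"), names(panel))
  if (length(miss)) stop("panel is missing columns: ", paste(miss, collapse = ", "))
  panel <- panel[order(panel$year, panel$county_id), ]
  X1 <- cbind("(Intercept)" = 1, as.matrix(panel[spec$regressors]))
  list(panel = panel, X1 = X1, yv = panel[[spec$dependent]],
       coords = cbind(x = panel$x, y = panel$y, t = as.numeric(panel$year)))
}

#' Adaptive bandwidth selection by leave-one-out cross-validation
#'
#' Searches a grid of adaptive neighbour counts `k` and space-time ratios
#' `tau = phi_t / phi_s`. For each candidate pair every observation is
#' predicted from a local weighted fit over its `k` nearest space-time
#' neighbours *excluding itself*, and the pair minimizing the sum of squared
#' prediction errors wins; ties go to the smaller `k`, then the smaller
#' `tau`.
#'
#' @param panel a `county_panel` with centroid columns `x`, `y`.
#' @param spec a [model_spec()].
#' @param k_candidates integer vector, each in `(p + 1, n_obs - 1]` where `p`
#'   is the number of regressors.
#' @param tau_candidates positive numeric vector of ratios `phi_t/phi_s`.
#' @param year_range optional `c(first, last)` restriction applied before
#'   selection (and to be applied equally in [fit_gtwr()]).
#' @return list of class `gtwr_bandwidth`: `k`, `tau`, `params`
#'   ([st_kernel_params()] with `phi_s = 1`), `cv_score`, and the full
#'   `cv_grid`.
#' @export
select_bandwidth <- function(panel, spec = model_spec(),
                             k_candidates, tau_candidates = 1,
                             year_range = NULL) {
  panel <- restrict_years(panel, year_range)
  d <- gtwr_design(panel, spec)
  n_obs <- nrow(d$X1)
  p1 <- ncol(d$X1)
  k_candidates <- sort(unique(as.integer(k_candidates)))
  if (any(k_candidates <= p1) || any(k_candidates > n_obs - 1L))
    stop("k candidates must lie in (p + 1, n_obs - 1]")
  if (any(tau_candidates <= 0)) stop("tau candidates must be positive")
  tau_candidates <- sort(unique(tau_candidates))

  grid <- expand.grid(k = k_candidates, tau = tau_candidates)
  grid$cv <- NA_real_
  for (tau in tau_candidates) {
    prm <- st_kernel_params(1, tau)
    # distances and neighbour orders once per tau, reused across k
    D2 <- matrix(0, n_obs, n_obs)
    for (i in seq_len(n_obs))
      D2[i, ] <- st_distances(d$coords[i, ], d$coords, prm)
    ORD <- apply(D2, 1, order)           # n_obs x n_obs, columns = focal
    for (k in k_candidates) {
      sse <- 0
      n_sing <- 0L
      for (i in seq_len(n_obs)) {
        ord <- ORD[, i]
        ord <- ord[ord != i]             # leave the focal observation out
        fit <- tryCatch(local_wls(d$X1, d$yv, D2[i, ], ord, k),
                        error = function(e) NULL)
        if (is.null(fit)) { n_sing <- n_sing + 1L; next }
        pred <- sum(d$X1[i, ] * fit$coef)
        sse <- sse + (d$yv[i] - pred)^2
      }
      if (n_sing == n_obs) stop("all candidate local fits singular at k = ", k)
      grid$cv[grid$k == k & grid$tau == tau] <- sse
    }
  }
  best <- grid[order(grid$cv, grid$k, grid$tau), ][1, ]
  structure(list(k = best$k, tau = best$tau,
                 params = st_kernel_params(1, best$tau),
                 cv_score = best$cv, cv_grid = grid),
            class = "gtwr_bandwidth")
}

#' @export
print.gtwr_bandwidth <- function(x, ...) {
  cat(sprintf("GTWR adaptive bandwidth: k = %d, tau = %g (CV SSE = %.4g)\n",
              x$k, x$tau, x$cv_score))
  invisible(x)
}

#' Geographically and temporally weighted regression
#'
#' Fits one weighted least-squares regression per observation over its `k`
#' nearest space-time neighbours (self included), with Gaussian kernel
#' weights `exp(-d^2/b^2)` and the adaptive radius `b` equal to the k-th
#' smallest combined distance. Local designs that turn singular fall back to
#' a ridge jitter of `1e-8` times the trace, counted in the result.
#'
#' @param panel a `county_panel` with centroid columns `x`, `y`.
#' @param spec a [model_spec()].
#' @param bandwidth a `gtwr_bandwidth` from [select_bandwidth()], or a list
#'   with elements `k` and `tau`. An optional element `fixed_b` replaces the
#'   adaptive radius by a fixed one (a very large `fixed_b` flattens the
#'   kernel, recovering pooled OLS in every local fit).
#' @param year_range optional `c(first, last)` year restriction (the panel's
#'   earliest years are commonly dropped when the full space-time weight
#'   matrix would be too large; restriction is a first-class option here).
#' @return object of class `gtwr_fit`: `local` data frame (county_id, year,
#'   intercept, one column per regressor, kernel weight sum, fitted,
#'   residual), `bandwidth`, global `r_squared` (1 - SSR/SST over all
#'   observations), `cv_score` (carried from selection when available), and
#'   `n_ridge_fallbacks`.
#' @export
fit_gtwr <- function(panel, spec = model_spec(), bandwidth,
                     year_range = NULL) {
  panel <- restrict_years(panel, year_range)
  d <- gtwr_design(panel, spec)
  n_obs <- nrow(d$X1)
  p1 <- ncol(d$X1)
  k <- as.integer(bandwidth$k)
  tau <- bandwidth$tau
  if (k <= p1 - 1L || k > n_obs)
    stop("bandwidth k must lie in (p, n_obs]")
  prm <- st_kernel_params(1, tau)
  fixed_b2 <- if (!is.null(bandwidth$fixed_b)) bandwidth$fixed_b^2 else NULL

  coefs <- matrix(NA_real_, n_obs, p1, dimnames = list(NULL, colnames(d$X1)))
  wsum <- fitted <- numeric(n_obs)
  ridge_counter <- new.env()
  ridge_counter$n <- 0L
  for (i in seq_len(n_obs)) {
    d2 <- st_distances(d$coords[i, ], d$coords, prm)
    ord <- order(d2)
    fit <- local_wls(d$X1, d$yv, d2, ord, k, ridge_counter, fixed_b2)
    coefs[i, ] <- fit$coef
    wsum[i] <- fit$wsum
    fitted[i] <- sum(d$X1[i, ] * fit$coef)
  }
  if (ridge_counter$n > 0L)
    warning(ridge_counter$n, " local designs required a ridge fallback")
  resid <- d$yv - fitted
  ssr <- sum(resid^2)
  sst <- sum((d$yv - mean(d$yv))^2)
  local <- data.frame(county_id = d$panel$county_id, year = d$panel$year,
                      as.data.frame(coefs), check.names = FALSE)
  local$weight_sum <- wsum
  local$fitted <- fitted
  local$residual <- resid
  out <- list(local = local, bandwidth = list(k = k, tau = tau, params = prm),
              r_squared = 1 - ssr / sst,
              cv_score = bandwidth$cv_score %||% NA_real_,
              n_ridge_fallbacks = ridge_counter$n,
              spec = spec)
  class(out) <- "gtwr_fit"
  out
}

#' @export
print.gtwr_fit <- function(x, ...) {
  cat(sprintf("GTWR fit: %d observations, k = %d, tau = %g, global R2 = %.3f\n",
              nrow(x$local), x$bandwidth$k, x$bandwidth$tau, x$r_squared))
  if (x$n_ridge_fallbacks > 0)
    cat(sprintf("  (%d local ridge fallbacks)\n", x$n_ridge_fallbacks))
  invisible(x)
}

#' Restrict a panel to a year range
#'
#' @param panel a `county_panel`.
#' @param year_range `NULL` (no restriction) or `c(first, last)`.
#' @return the restricted panel.
#' @export
restrict_years <- function(panel, year_range = NULL) {
  if (is.null(year_range)) return(panel)
  stopifnot(length(year_range) == 2L)
  panel[panel$year >= year_range[1] & panel$year <= year_range[2], ]
}

#' Serialize a GTWR fit
#'
#' Writes the per-observation local coefficients as CSV and the fit metadata
#' (k, tau, CV score, global R2) as a JSON sidecar.
#'
#' @param fit a `gtwr_fit`.
#' @param csv_path,json_path output paths.
#' @export
write_gtwr <- function(fit, csv_path, json_path = NULL) {
  if (!is.null(csv_path)) write.csv(fit$local, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(k = fit$bandwidth$k, tau = fit$bandwidth$tau,
           cv_score = fit$cv_score, r_squared = fit$r_squared,
           n_ridge_fallbacks = fit$n_ridge_fallbacks),
      json_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(csv_path)
}
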