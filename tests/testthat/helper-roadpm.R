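# shared fixtures: tiny lattices, iid covariates, and quick DGP wrappers

quick_weights <- function(n_rows, n_cols, cell_km = 50) {
  row_standardize(queen_weights(make_lattice(n_rows, n_cols, cell_km)))
}

# two iid standard-normal regressors; the cleanest design for estimator
# recovery checks
covfun_iid <- function(geometry, years) {
  n <- length(geometry$county_id)
  T <- length(years)
  data.frame(county_id = rep(geometry$county_id, T),
             year = rep(years, each = n),
             x1 = rnorm(n * T), x2 = rnorm(n * T))
}

spec_iid <- function() model_spec(regressors = c("x1", "x2"))

sim_iid_panel <- function(geometry, years, w, lambda, rho, sigma_nu = 1,
                          sigma_alpha = 1, seed = 1,
                          beta = c(x1 = 1, x2 = -2)) {
  p <- dgp_params(beta = beta, lambda = lambda, rho = rho,
                  sigma_nu = sigma_nu, sigma_alpha = sigma_alpha,
                  gamma_alpha = 0, base_level = 25,
                  covariates = covfun_iid, seed = seed)
  simulate_panel(geometry, years, p, w)
}

# Moran-style residual spatial correlation: correlation of a vector with its
# spatial lag, pooled over years (independent check, not a package function)
lag_correlation <- function(values, w, n, T) {
  lagged <- unlist(lapply(seq_len(T), function(ti) {
    idx <- ((ti - 1) * n + 1):(ti * n)
    spatial_lag(w, values[idx])
  }))
  cor(values, lagged)
}
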