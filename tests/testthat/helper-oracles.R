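# Shared oracles and builders for the test suite.  Everything here is an
# independent re-derivation (dense linear algebra, no shortcuts) so that the
# package's optimized code paths are checked against first-principles math.

# log N(x; mean, Sigma) via dense Cholesky
dmvnorm_log <- function(x, mean, Sigma) {
  R <- chol(Sigma)
  w <- backsolve(R, x - mean, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(R))) + sum(w^2))
}

# one inverse-Wishart draw with df nu and scale S (matches the convention
# used for the V prior: density proportional to |V|^-(nu+p+1)/2 exp(-tr(S V^-1)/2))
riwish1 <- function(nu, S) {
  W <- stats::rWishart(1, nu, solve(S))[, , 1]
  solve(W)
}

# relative error in the Frobenius / L2 norm
rel_err <- function(est, truth) {
  sqrt(sum((est - truth)^2)) / sqrt(sum(truth^2))
}

# a small fully-featured probit model with one non-spatial level
tiny_probit_model <- function(n_y = 30, n_s = 4, n_c = 2, n_f = 2,
                              seed = 42, with_C = FALSE) {
  ds <- generate_dataset(n_y, n_s, n_c = n_c, n_t = 2,
                         level_spec = list(spatial_method = "none",
                                           n_factors = n_f),
                         response = "probit", seed = seed,
                         use_taxonomy = with_C)
  build_model(ds$data$Y, ds$data$X, ds$data$Tr, ds$data$C, list(ds$level),
              response = "probit")
}

# a small spatial probit model (gp / pgp / nngp)
tiny_spatial_model <- function(method, n_y = 25, n_s = 3, n_f = 2,
                               seed = 7, alpha_grid_n = 5) {
  ds <- generate_dataset(n_y, n_s, n_c = 2, n_t = 1,
                         level_spec = list(spatial_method = method,
                                           n_factors = n_f, alpha = 0.3,
                                           n_neighbours = 5, n_knots = 9),
                         response = "probit", seed = seed)
  pr <- default_priors(2, 1, ds$level$n_units, list(ds$level$coords),
                       alpha_grid_n = alpha_grid_n)
  build_model(ds$data$Y, ds$data$X, ds$data$Tr, NULL, list(ds$level),
              response = "probit", priors = pr)
}
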