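# shared fixtures: tiny conjugate models and toy first-level posteriors

# linear-Gaussian model y = X theta + e with known noise variance; exact
# posterior and log evidence, the oracle for Bayesian model reduction
conjugate_fit <- function(X, y, prior_mean, prior_cov, noise_var) {
  P <- solve(prior_cov) + crossprod(X) / noise_var
  C <- solve(P)
  m <- C %*% (solve(prior_cov, prior_mean) + crossprod(X, y) / noise_var)
  V <- X %*% prior_cov %*% t(X) + diag(noise_var, nrow(X))
  r <- y - X %*% prior_mean
  lev <- -0.5 * (nrow(X) * log(2 * pi) +
                   as.numeric(determinant(V)$modulus) +
                   as.numeric(t(r) %*% solve(V, r)))
  list(mean = as.numeric(m), cov = C, log_evidence = lev)
}

# lightweight stand-in for an inversion result (group-level tests)
toy_fit <- function(mean, sd = 0.05, prior_var = 1 / 64) {
  p <- length(mean)
  list(mean = stats::setNames(mean, paste0("p", seq_len(p))),
       cov = diag(sd^2, p),
       prior = list(mean = rep(0, p), cov = diag(prior_var, p)),
       n_regions = NULL)
}

# one simulated two-node dataset at the default study conditions
sim_csd <- function(seed, net = soz_network(), volumes = 300, runs = 2) {
  ds <- simulate_dataset(net, acquisition_spec(volumes_per_run = volumes,
                                               n_runs = runs, seed = seed))
  estimate_csd_mar(concatenate_runs(ds$runs))
}
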