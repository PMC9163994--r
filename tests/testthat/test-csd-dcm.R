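test_that("decoupled nodes predict zero cross-spectra and -0.5 Hz decay", {
  pr <- dcm_priors(2)
  g <- predict_csd(pr$mean, default_freq_grid(2), 2)
  expect_true(all(Mod(g$matrices[1, 2, ]) == 0))
  # a_self_log = 0 decodes to exactly -0.5 Hz
  fit_like <- list(mean = pr$mean, pp = rep(0.5, 14), labels = c("R1", "R2"),
                   n_regions = 2L, cov = pr$cov)
  ce <- coupling_estimates(fit_like)
  expect_equal(ce$hz[ce$self], c(-0.5, -0.5))
})

test_that("parameter posterior probabilities follow the Gaussian tail", {
  expect_equal(parameter_posterior_prob(0, 1), 0.5)
  expect_equal(parameter_posterior_prob(1, 1), pnorm(1), tolerance = 1e-12)
  expect_equal(round(parameter_posterior_prob(1, 1), 3), 0.841)
  expect_gt(parameter_posterior_prob(5, 0.1), 0.999999)
  expect_warning(p <- parameter_posterior_prob(1, 0), "degenerate")
  expect_identical(p, 1)
})

test_that("the ensemble cross-spectrum matches the analytic prediction", {
  # average MAR spectra over replicates of a long noiseless recording and
  # compare with the generative model at the true parameters, mid-band
  net <- soz_network(noise_amp = 0)
  freq <- default_freq_grid(2)
  nrep <- 12
  S <- array(0, c(2, 2, length(freq)))
  for (s in seq_len(nrep)) {
    ds <- simulate_dataset(net, acquisition_spec(volumes_per_run = 1500,
                                                 n_runs = 1, seed = s,
                                                 run_offset_sd = 0))
    # raw (unstandardized) spectra: undo the recorded scaling
    csd <- estimate_csd_mar(concatenate_runs(ds$runs))
    D <- diag(csd$scales)
    for (k in seq_along(freq))
      S[, , k] <- S[, , k] + (D %*% csd$matrices[, , k] %*% D) / nrep
  }
  th <- dcm_priors(2, c("SOZ", "pZ"))$mean
  th["a[pZ<-SOZ]"] <- 0.22; th["a[SOZ<-pZ]"] <- -0.73
  th[c("fluct_amp[SOZ]", "fluct_amp[pZ]")] <- log(1e-5)
  th[c("noise_amp[SOZ]", "noise_amp[pZ]")] <- -40
  g <- predict_csd(th, freq, 2, labels = c("SOZ", "pZ"))$matrices
  mid <- freq >= 0.02 & freq <= 0.15
  for (i in 1:2) {
    rel <- abs(Re(S[i, i, mid]) / Re(g[i, i, mid]) - 1)
    expect_lt(mean(rel), 0.10)
  }
  rel12 <- Mod(S[1, 2, mid] - g[1, 2, mid]) / Mod(g[1, 2, mid])
  expect_lt(mean(rel12), 0.10)
  # phase information (the directional signature) agrees in sign
  expect_true(all(sign(Im(S[1, 2, mid])) == sign(Im(g[1, 2, mid]))))
})

test_that("inversion is self-consistent on model-generated data", {
  pr <- dcm_priors(2, c("SOZ", "pZ"))
  # data generated exactly at the prior mean: every posterior mean must
  # fall within 2 posterior SD of the truth
  g0 <- predict_csd(pr$mean, default_freq_grid(2), 2,
                    labels = c("SOZ", "pZ"))
  f0 <- invert_dcm(g0, pr)
  expect_true(f0$converged)
  expect_true(all(abs(f0$mean - pr$mean) <= 2 * sqrt(diag(f0$cov)) + 1e-8))
  # ascent is monotone up to the wobble of the Laplace approximation
  # (the trace mixes refreshed Jacobians near convergence)
  expect_true(all(diff(f0$accepted_F) > -0.05))
  # strong asymmetric couplings: signs recovered, magnitudes shrunk
  # toward zero by the deliberate coupling priors
  th <- pr$mean
  th["a[pZ<-SOZ]"] <- 0.22; th["a[SOZ<-pZ]"] <- -0.73
  g <- predict_csd(th, default_freq_grid(2), 2, labels = c("SOZ", "pZ"))
  fit <- invert_dcm(g, pr)
  expect_true(fit$converged)
  expect_gt(fit$mean["a[pZ<-SOZ]"], 0.05)
  expect_lt(fit$mean["a[SOZ<-pZ]"], -0.2)
  expect_true(all(diff(fit$accepted_F) > -0.05))
})

test_that("inversion is deterministic and invariant to data rescaling", {
  csd <- sim_csd(3)
  f1 <- invert_dcm(csd)
  f2 <- invert_dcm(csd)
  expect_equal(f1$free_energy, f2$free_energy, tolerance = 1e-6)
  expect_identical(f1$mean, f2$mean)
  # rescaling the input series by a constant leaves couplings unchanged
  scaled <- csd
  scaled$matrices <- csd$matrices * 7.3^2
  f3 <- invert_dcm(scaled)
  expect_lt(max(abs(f3$mean[1:2] - f1$mean[1:2])), 1e-3)
})

test_that("swapping the two regions permutes the posterior", {
  csd <- sim_csd(8)
  perm <- csd
  perm$matrices <- csd$matrices[2:1, 2:1, , drop = FALSE]
  perm$labels <- csd$labels[2:1]
  perm$scales <- csd$scales[2:1]
  f1 <- invert_dcm(csd)
  f2 <- invert_dcm(perm)
  # map: a[2<-1] <-> a[1<-2]; per-region blocks swap within themselves
  swap <- c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9, 12, 11, 14, 13)
  expect_lt(max(abs(unname(f2$mean) - unname(f1$mean[swap]))), 1e-6)
  expect_equal(f1$free_energy, f2$free_energy, tolerance = 1e-6)
})

test_that("observation noise widens coupling posteriors", {
  mean_sd <- function(noise_amp) {
    sds <- sapply(1:10, function(s) {
      net <- soz_network(noise_amp = noise_amp)
      csd <- sim_csd(s + 60, net = net, volumes = 300, runs = 1)
      fit <- invert_dcm(csd)
      mean(sqrt(diag(fit$cov))[1:2])
    })
    mean(sds)
  }
  ladder <- c(2e-7, 2e-6, 2e-5)
  sds <- vapply(ladder, mean_sd, numeric(1))
  expect_true(sds[1] < sds[2] && sds[2] < sds[3])
})

test_that("dimension mismatches and invalid data are rejected", {
  csd <- sim_csd(2, volumes = 150, runs = 1)
  bad_prior <- dcm_priors(3)
  expect_error(invert_dcm(csd, bad_prior), "dimension")
  m <- csd$matrices
  m[1, 2, 1] <- m[1, 2, 1] + 1      # break Hermitian symmetry
  expect_error(cross_spectral_density(csd$freq_hz, m), "Hermitian")
})
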