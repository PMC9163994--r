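test_that("null dynamics stay identically zero", {
  net <- ground_truth_network(matrix(0, 2, 2), fluct_amp = 1e-12)
  net$fluct_amp <- c(0, 0)            # zero drive after validation
  sim <- simulate_neural(net, duration = 20, seed = 1)
  expect_true(all(sim$states == 0))
})

test_that("simulation is bit-identical under a fixed seed", {
  net <- soz_network()
  a <- simulate_neural(net, duration = 30, seed = 7)
  b <- simulate_neural(net, duration = 30, seed = 7)
  expect_identical(a$states, b$states)
  acq <- acquisition_spec(volumes_per_run = 32, n_runs = 2, seed = 3)
  r1 <- simulate_dataset(net, acq)$runs
  r2 <- simulate_dataset(net, acq)$runs
  expect_identical(r1[[1]]$values, r2[[1]]$values)
  expect_identical(r1[[2]]$values, r2[[2]]$values)
})

test_that("unstable networks are rejected with a stability diagnostic", {
  A <- matrix(c(0, 2, 2, 0), 2, 2)
  expect_error(ground_truth_network(A), "unstable")
  net <- soz_network()
  net$a_offdiag[1, 2] <- 5            # destabilize after construction
  expect_error(simulate_neural(net, 10, seed = 1), "unstable")
})

test_that("lagged cross-covariance sign matches the Lyapunov oracle", {
  # A = [[-0.5, 0], [0.2, -0.5]]: region 1 drives region 2 with +0.2 Hz
  A <- matrix(c(-0.5, 0.2, 0, -0.5), 2, 2)
  net <- ground_truth_network(matrix(c(0, 0.2, 0, 0), 2, 2),
                              a_self_log = 0, fluct_exp = 0)
  # continuous-time Lyapunov oracle: A P + P A' + Q = 0 solved by
  # vectorization; lagged covariance C(tau) = expm(A tau) P
  Q <- diag(2)
  P <- matrix(solve(kronecker(diag(2), A) + kronecker(A, diag(2)),
                    -as.vector(Q)), 2, 2)
  tau <- 0.5
  eA <- diag(2); term <- diag(2)      # matrix exponential by series
  for (k in 1:30) { term <- term %*% (A * tau) / k; eA <- eA + term }
  C_tau <- eA %*% P                   # cov(x(t + tau), x(t))
  oracle_sign <- sign(C_tau[2, 1])    # region1 -> region2, lag tau

  sim <- simulate_neural(net, duration = 4000, dt = 0.1, seed = 42)
  x <- sim$states
  lag <- round(tau / sim$dt)
  n <- ncol(x)
  emp <- mean(x[2, (lag + 1):n] * x[1, 1:(n - lag)])
  expect_identical(sign(emp), oracle_sign)
})

test_that("sampling produces the requested runs and is exact without noise", {
  net <- soz_network(noise_amp = 0)
  acq <- acquisition_spec(volumes_per_run = 300, n_runs = 2, seed = 1,
                          run_offset_sd = 0)
  ds <- simulate_dataset(net, acq)
  expect_length(ds$runs, 2L)
  expect_identical(ncol(ds$runs[[1]]$values), 300L)
  expect_identical(ncol(ds$runs[[2]]$values), 300L)
  # zero noise, zero offsets: decimated BOLD at the TR grid, exactly
  step <- acq$tr_seconds / ds$bold$dt
  idx <- seq(1, by = step, length.out = 300)
  expect_equal(ds$runs[[1]]$values[1, ], ds$bold$bold[1, idx],
               ignore_attr = TRUE)
  # insufficient duration errors
  short <- simulate_bold(net, duration = 100, seed = 1)
  expect_error(sample_runs(short, net, acq), "too short")
})

test_that("pure-noise sampling reproduces the specified power law", {
  # ensemble-average periodogram of noise-only output against the
  # closed-form two-sided PSD, averaged within frequency bands
  net <- soz_network(fluct_amp = 1e-12, noise_amp = 2, noise_exp = 1)
  net$fluct_amp <- c(0, 0)
  acq <- acquisition_spec(volumes_per_run = 256, n_runs = 1,
                          run_offset_sd = 0)
  nrep <- 100
  n <- 256; tr <- 2
  psum <- numeric(n %/% 2 - 1)
  set.seed(5)
  for (r in seq_len(nrep)) {
    acq$seed <- r
    run <- sample_runs(list(bold = matrix(0, 2, n * 10), dt = 0.2),
                       net, acq)[[1]]
    x <- run$values[1, ] - mean(run$values[1, ])
    P <- Mod(stats::fft(x))^2 * tr / n
    psum <- psum + P[2:(n %/% 2)] / nrep
  }
  f <- (1:(n %/% 2 - 1)) / (n * tr)
  target <- 2 * f^(-1)
  mid <- f > 0.02 & f < 0.15
  bands <- cut(f[mid], breaks = quantile(f[mid], seq(0, 1, 0.25)),
               include.lowest = TRUE)
  ratio <- tapply(psum[mid], bands, mean) / tapply(target[mid], bands, mean)
  expect_true(all(abs(ratio - 1) < 0.10))
})

test_that("ROI voxel fixtures behave as constructed", {
  x <- sin(seq(0, 10, length.out = 200))
  m <- make_roi_voxels(x, 1, weights = 1, noise_sd = 0)
  expect_equal(m[1, ], x)
  m2 <- make_roi_voxels(x, 8, weights = seq(0.5, 2, length.out = 8),
                        noise_sd = 0)
  s <- svd(m2 - rowMeans(m2))
  expect_lt(s$d[2] / s$d[1], 1e-10)   # exactly rank one
  # SNR 2: eigenvariate still tracks the source closely
  m3 <- make_roi_voxels(x, 50, weights = 1, noise_sd = sd(x) / 2,
                        seed = 9)
  ev <- extract_eigenvariate(m3)
  expect_gt(abs(cor(ev$series, x)), 0.95)
})

test_that("balloon impulse response peaks at the expected latency", {
  imp <- hemodynamic_impulse(dt = 0.1)
  peak <- imp$time[which.max(imp$response)]
  expect_gt(peak, 4); expect_lt(peak, 6)
  fine <- hemodynamic_impulse(dt = 0.05)
  peak2 <- fine$time[which.max(fine$response)]
  expect_lt(abs(peak2 - peak) / peak, 0.02)
  # zero input, zero output
  y <- hemodynamic_response(matrix(0, 2, 50), dt = 0.1)
  expect_true(all(abs(y) < 1e-12))
  # local linearity: response to a scaled small impulse is proportional
  x <- matrix(0, 1, 200); x[1, 5] <- 0.01
  y1 <- hemodynamic_response(x, 0.1)
  y2 <- hemodynamic_response(10 * x, 0.1)
  expect_lt(max(abs(y2 - 10 * y1)) / max(abs(y2)), 0.01)
})

test_that("simulated output stays bounded over long horizons", {
  net <- soz_network()
  s1 <- simulate_neural(net, duration = 200, seed = 2)
  s2 <- simulate_neural(net, duration = 2000, seed = 2)
  expect_lt(max(abs(s2$states)), 10 * max(abs(s1$states)) + 1)
  expect_true(all(is.finite(s2$states)))
})
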