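test_that("model construction validates dimensions, noise and stationarity", {
  m <- mvar_model(matrix(0, 8, 8))
  expect_s3_class(m, "mvar_model")
  expect_identical(m$p, 1L)
  expect_true(m$stationary)

  # unidirectional ring of weight 0.25: companion eigenvalues are
  # 0.25 * (8th roots of unity), all of modulus 0.25
  ring <- make_network("uni_ring")
  ev <- eigen(ring$coeffs[[1]], only.values = TRUE)$values
  expect_equal(sort(Mod(ev)), rep(0.25, 8), tolerance = 1e-12)
  expect_equal(spectral_radius(ring), 0.25, tolerance = 1e-12)

  expect_error(mvar_model(diag(8)), "not stationary")  # random walk
  expect_error(mvar_model(list(matrix(0, 2, 2), matrix(0, 3, 3))),
               "not 2x2")
  expect_error(mvar_model(matrix(0, 2, 2), matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
  expect_error(mvar_model(matrix(0, 2, 2), matrix(c(1, 0, 0.5, 1), 2)),
               "not symmetric")
})

test_that("spectral radius matches scalar and polynomial-root oracles", {
  expect_equal(spectral_radius(mvar_model(matrix(0, 3, 3))), 0)
  expect_equal(spectral_radius(mvar_model(matrix(0.5), matrix(1))), 0.5)

  # AR(2): companion radius equals max root modulus of z^2 - a1 z - a2
  a1 <- 0.5; a2 <- 0.3
  m <- mvar_model(list(matrix(a1), matrix(a2)), matrix(1))
  roots <- polyroot(c(-a2, -a1, 1))
  expect_equal(spectral_radius(m), max(Mod(roots)), tolerance = 1e-10)
})

test_that("companion embedding has the documented block structure", {
  A <- matrix(c(0.2, 0.1, 0, 0.3), 2)
  m <- mvar_model(list(A), diag(2))
  cf1 <- companion(m, r = 1)
  expect_equal(cf1$big_coeff, A)
  expect_equal(cf1$big_noise_cov, diag(2))

  cf3 <- companion(m, r = 3)
  expect_equal(dim(cf3$big_coeff), c(6L, 6L))
  expect_equal(cf3$big_coeff[1:2, 1:2], A)
  expect_equal(cf3$big_coeff[1:2, 3:6], matrix(0, 2, 4))  # lags 2,3 absent
  expect_equal(cf3$big_coeff[3:6, 1:4], diag(4))          # shift identity
  expect_equal(cf3$big_noise_cov[3:6, 3:6], matrix(0, 4, 4))
  expect_error(companion(m, r = 0), "below the model order")

  # MVAR(2): companion eigenvalues are inverse roots of det(I - A1 z - A2 z^2)
  m2 <- random_stable_model(3, 2, seed = 11)
  ev <- eigen(companion(m2)$big_coeff, only.values = TRUE)$values
  detpoly <- function(z) prod(eigen(diag(3) - m2$coeffs[[1]] * z -
                                      m2$coeffs[[2]] * z^2,
                                    only.values = TRUE)$values)
  for (lambda in ev[Mod(ev) > 1e-8])
    expect_lt(Mod(detpoly(1 / lambda)), 1e-8)
})

test_that("stationary moments solve the Lyapunov fixed point", {
  # zero dynamics: sigma = noise, all lagged covariances vanish
  m0 <- mvar_model(matrix(0, 4, 4))
  for (tau in c(1, 3)) {
    mom <- stationary_moments(m0, tau)
    expect_matrix_equal(mom$sigma, diag(4), 1e-12)
    expect_matrix_equal(mom$sigma_tau, matrix(0, 4, 4), 1e-12)
  }

  # univariate AR(1) closed form: sigma = 1/(1-a^2), sigma_tau = a^tau sigma
  m1 <- mvar_model(matrix(0.5), matrix(1))
  mom1 <- stationary_moments(m1, 1)
  expect_equal(drop(mom1$sigma), 4 / 3, tolerance = 1e-12)
  expect_equal(drop(mom1$sigma_tau), 2 / 3, tolerance = 1e-12)
  expect_equal(drop(stationary_moments(m1, 4)$sigma_tau), 0.5^4 * 4 / 3,
               tolerance = 1e-12)

  expect_error(stationary_moments(m1, 0.5), "positive integer")
})

test_that("Lyapunov solution agrees with the truncated-series oracle", {
  cases <- list(c(n = 2, p = 1), c(n = 4, p = 2), c(n = 8, p = 3),
                c(n = 5, p = 1))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    m <- random_stable_model(cs[["n"]], cs[["p"]], seed = 100 + i)
    cf <- companion(m)
    S_oracle <- series_stationary_cov(cf$big_coeff, cf$big_noise_cov)
    mom <- stationary_moments(m, tau = 1)
    n <- m$n
    expect_matrix_equal(mom$sigma, S_oracle[1:n, 1:n], 1e-8)
    # solution is symmetric positive definite
    expect_matrix_equal(mom$sigma, t(mom$sigma), 1e-12)
    expect_true(all(eigen(mom$sigma, only.values = TRUE)$values > 0))
    if (m$p >= 2) {
      # lag-1 block of the companion solution = Cov(X_{t-1}, X_t)
      expect_matrix_equal(mom$sigma_tau, S_oracle[(n + 1):(2 * n), 1:n],
                          1e-8)
    }
  }
})

test_that("higher-lag moments follow the Yule-Walker recursion", {
  # MVAR(2), tau beyond the companion order: compare with the big
  # embedding solved at a larger order
  m <- random_stable_model(3, 2, seed = 7)
  tau <- 4
  mom <- stationary_moments(m, tau)
  cf_big <- companion(m, r = tau + 1)
  bigQ <- matrix(0, 3 * (tau + 1), 3 * (tau + 1))
  bigQ[1:3, 1:3] <- m$noise_cov
  S_big <- series_stationary_cov(cf_big$big_coeff, bigQ)
  expect_matrix_equal(mom$sigma_tau,
                      S_big[(tau * 3 + 1):((tau + 1) * 3), 1:3], 1e-7)
})

test_that("simulation is deterministic, stationary, and moment-consistent", {
  net <- make_network("recip_ring")
  a <- simulate_mvar(net, 500, trials = 2, seed = 99)
  b <- simulate_mvar(net, 500, trials = 2, seed = 99)
  expect_identical(a$values, b$values)
  expect_false(identical(
    a$values, simulate_mvar(net, 500, trials = 2, seed = 100)$values))

  # zero-coefficient model with identity noise: empirical covariance ~ I
  m0 <- mvar_model(matrix(0, 4, 4))
  x <- simulate_mvar(m0, 1e5, seed = 1)$values[[1]]
  expect_lt(max(abs(cov(x) - diag(4))), 0.05)

  # reciprocal ring: empirical covariance within 5% Frobenius of analytic
  xr <- simulate_mvar(net, 1e4, seed = 2)$values[[1]]
  S_true <- stationary_moments(net, 1)$sigma
  expect_lt(norm(cov(xr) - S_true, "F") / norm(S_true, "F"), 0.05)

  walk <- suppressWarnings(mvar_model(diag(2), allow_nonstationary = TRUE))
  expect_error(simulate_mvar(walk, 100), "non-stationary")
})

test_that("simulate-then-estimate error decreases with series length", {
  net <- make_network("uni_ring")
  S_true <- stationary_moments(net, 1)$sigma
  errs <- vapply(c(1e3, 1e4, 1e5), function(Tn) {
    x <- simulate_mvar(net, Tn, seed = 5)$values[[1]]
    norm(cov(x) - S_true, "F")
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("exponential innovations give right-skewed stationary marginals", {
  net <- make_network("uni_ring")
  x <- simulate_mvar(net, 3000, noise = noise_spec("exponential"),
                     seed = 3)$values[[1]]
  skew <- apply(x, 2, function(v) mean((v - mean(v))^3) / sd(v)^3)
  expect_true(all(skew > 0.5))
  expect_error(noise_spec("exponential", covariance = diag(2)),
               "must not be supplied")
})
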