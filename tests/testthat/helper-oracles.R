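# independent oracles and small model builders used across tests

# stationary covariance by truncated series sum(A^k Q (A')^k), independent
# of the Lyapunov solver in the package
series_stationary_cov <- function(A, Q, tol = 1e-12, max_terms = 10000) {
  S <- Q
  term <- Q
  for (k in seq_len(max_terms)) {
    term <- A %*% term %*% t(A)
    S <- S + term
    if (max(abs(term)) < tol) break
  }
  S
}

# random stable MVAR(p) model: scale coefficients until the companion
# spectral radius is comfortably below 1
random_stable_model <- function(n, p, seed) {
  set.seed(seed)
  coeffs <- replicate(p, matrix(rnorm(n * n, sd = 0.3 / p), n, n),
                      simplify = FALSE)
  repeat {
    m <- tryCatch(phitime::mvar_model(coeffs), error = function(e) NULL)
    if (!is.null(m) && spectral_radius(m) < 0.9) return(m)
    coeffs <- lapply(coeffs, function(A) A * 0.7)
  }
}

# brute-force Phi-E over all bipartitions, written from the defining
# formulas with plain determinants -- an independent code path from
# phi_from_moments()
brute_force_phi_e <- function(sigma, sigma_tau) {
  n <- nrow(sigma)
  mi <- function(idx) {
    S <- sigma[idx, idx, drop = FALSE]
    St <- sigma_tau[idx, idx, drop = FALSE]
    cond <- S - St %*% solve(S) %*% t(St)
    0.5 * log(det(S) / det(cond))
  }
  ent <- function(idx) {
    S <- sigma[idx, idx, drop = FALSE]
    0.5 * log((2 * pi * exp(1))^length(idx) * det(S))
  }
  whole <- seq_len(n)
  best <- NULL
  # enumerate subsets of {2..n} joined with element 1 as part1
  for (mask in 0:(2^(n - 1) - 1)) {
    p1 <- c(1L, which(bitwAnd(mask, 2^(0:(n - 2))) > 0) + 1L)
    p2 <- setdiff(whole, p1)
    if (length(p2) == 0) next
    ei <- mi(whole) - mi(p1) - mi(p2)
    K <- min(ent(p1), ent(p2))
    if (K <= 1e-6) next
    nei <- ei / K
    if (is.null(best) || nei < best$nei - 1e-15)
      best <- list(ei = ei, nei = nei, part1 = p1, part2 = p2)
  }
  best
}

expect_matrix_equal <- function(object, expected, tol = 1e-8) {
  expect_lt(max(abs(object - expected)), tol)
}
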