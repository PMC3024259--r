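test_that("bipartition enumeration is canonical, complete and ordered", {
  expect_length(enumerate_bipartitions(2), 1)
  expect_length(enumerate_bipartitions(4), 7)
  expect_length(enumerate_bipartitions(8), 127)
  expect_error(enumerate_bipartitions(1), "at least 2")
  expect_error(enumerate_bipartitions(25), "refused")

  bips <- enumerate_bipartitions(5)
  for (b in bips) {
    expect_true(1L %in% b$part1)
    expect_identical(b$part1, sort(b$part1))
    expect_identical(sort(c(b$part1, b$part2)), 1:5)
    expect_gt(length(b$part2), 0)
  }
  sizes <- vapply(bips, function(b) length(b$part1), integer(1))
  expect_identical(sizes, sort(sizes))  # ordered by |part1|
  keys <- vapply(bips, function(b)
    paste(b$part1, collapse = ","), character(1))
  expect_identical(anyDuplicated(keys), 0L)
})

test_that("effective information vanishes on decomposing bipartitions", {
  # two independent 4-element sub-systems, block-diagonal everything
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- make_network("uni_ring", n = 4)$coeffs[[1]]
  A[5:8, 5:8] <- make_network("recip_ring", n = 4, weight = 0.2)$coeffs[[1]]
  mom <- stationary_moments(mvar_model(A), 1)
  split <- list(part1 = 1:4, part2 = 5:8)
  expect_lt(abs(effective_information(mom, split)), 1e-9)
  expect_lt(abs(stochastic_interaction(mom, split)), 1e-9)
})

test_that("two-element effective information matches the symbolic form", {
  m <- random_stable_model(2, 1, seed = 61)
  mom <- stationary_moments(m, 1)
  S <- mom$sigma; St <- mom$sigma_tau
  b <- list(part1 = 1L, part2 = 2L)
  # symbolic: whole MI via 2x2 determinants, scalar part MIs
  det2 <- function(M) M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  J <- rbind(cbind(S, St), cbind(t(St), S))
  detJ <- det(J)  # 4x4, direct
  mi_whole <- 0.5 * log(det2(S)^2 / detJ)
  mi_1 <- 0.5 * log(S[1, 1]^2 / (S[1, 1]^2 - St[1, 1]^2))
  mi_2 <- 0.5 * log(S[2, 2]^2 / (S[2, 2]^2 - St[2, 2]^2))
  expect_equal(effective_information(mom, b), mi_whole - mi_1 - mi_2,
               tolerance = 1e-10)
})

test_that("normalization K picks the smaller part entropy and scales with variance", {
  net <- make_network("recip_ring")
  mom <- stationary_moments(net, 1)

  # symmetric equal halves: labeling order is irrelevant
  b <- list(part1 = c(1L, 2L, 3L, 4L), part2 = c(5L, 6L, 7L, 8L))
  b_swap <- list(part1 = b$part2, part2 = b$part1)
  expect_equal(normalization_K(mom, b), normalization_K(mom, b_swap))

  # 1-vs-7: the single element has the smaller entropy
  b17 <- list(part1 = 1L, part2 = 2:8)
  expect_equal(normalization_K(mom, b17),
               gaussian_entropy(mom$sigma[1, 1, drop = FALSE]))
  expect_lt(normalization_K(mom, b17),
            gaussian_entropy(mom$sigma[2:8, 2:8]))

  # scaling all variances by c > 1 strictly increases K
  mom_scaled <- mom
  mom_scaled$sigma <- mom$sigma * 2.5
  expect_gt(normalization_K(mom_scaled, b), normalization_K(mom, b))
})

test_that("the MIB search agrees with an independent brute-force path", {
  for (seed in 62:64) {
    m <- random_stable_model(4, 1, seed)
    mom <- stationary_moments(m, 1)
    res <- phi_from_moments(mom)
    oracle <- brute_force_phi_e(mom$sigma, mom$sigma_tau)
    expect_equal(res$value, oracle$ei, tolerance = 1e-9)
    expect_identical(sort(res$mib$part1), sort(oracle$part1))
  }
})

test_that("phi results carry a coherent record table", {
  res <- phi_analytic(make_network("uni_ring"))
  expect_s3_class(res, "phi_result")
  expect_identical(nrow(res$records), 127L)
  expect_true(all(res$records$K > 0))
  mib_row <- res$records[res$records$is_mib, ]
  expect_identical(nrow(mib_row), 1L)
  expect_equal(mib_row$ei, res$value)
  expect_equal(min(res$records$normalized_ei, na.rm = TRUE),
               mib_row$normalized_ei)
  # broom-style accessors
  expect_identical(tidy(res), res$records)
  g <- glance(res)
  expect_identical(g$value, res$value)
  expect_identical(g$n_bipartitions, 127L)
})

test_that("zero dynamics carry zero integrated information", {
  res <- phi_from_moments(stationary_moments(mvar_model(matrix(0, 4, 4)), 1))
  expect_equal(res$value, 0)
})

test_that("phi_ar is computed by the identical path as phi_e", {
  net <- make_network("recip_ring")
  data <- simulate_mvar(net, 1500, trials = 3, seed = 65)
  r_e <- phi_empirical(data, measure = "phi_e")
  r_ar <- phi_empirical(data, measure = "phi_ar")
  expect_identical(r_e$values, r_ar$values)  # bit-identical
  expect_identical(r_ar$results[[1]]$measure, "phi_ar")
})

test_that("phi from time-reversed data equals phi from the original data", {
  net <- make_network("uni_ring")
  data <- simulate_mvar(net, 2000, trials = 2, seed = 66)
  rev_data <- phi_ts(lapply(data$values, function(v) v[nrow(v):1, ]))
  f <- phi_empirical(data, mode = "pooled")$value
  b <- phi_empirical(rev_data, mode = "pooled")$value
  expect_equal(f, b, tolerance = 1e-8)
})

test_that("per-trial and pooled empirical modes are both available", {
  net <- make_network("uni_ring")
  data <- simulate_mvar(net, 1500, trials = 4, seed = 67)
  per <- phi_empirical(data, mode = "per_trial")
  expect_s3_class(per, "phi_result_set")
  expect_length(per$values, 4)
  expect_equal(per$summary$mean, mean(per$values))
  expect_identical(nrow(tidy(per)), 4L)
  pooled <- phi_empirical(data, mode = "pooled")
  expect_s3_class(pooled, "phi_result")
  # pooled uses 4x the pairs of any single trial
  expect_identical(pooled$provenance$T_effective, 4L * 1499L)
})

test_that("near-tied normalized minima with distinct raw values exist", {
  # reciprocal ring with element 1's couplings weakened: near the switch
  # point, the single-element split and the balanced split have normalized
  # effective information within 3% while raw values differ by over 20%
  weaken <- function(g) {
    A <- make_network("recip_ring")$coeffs[[1]]
    A[1, ] <- A[1, ] * g
    A[, 1] <- A[, 1] * g
    mvar_model(A)
  }
  mom <- stationary_moments(weaken(0.37), 1)
  res <- phi_from_moments(mom)
  rec <- res$records
  o <- order(rec$normalized_ei)
  top2 <- rec[o[1:2], ]
  expect_lt(abs(top2$normalized_ei[1] - top2$normalized_ei[2]) /
              top2$normalized_ei[2], 0.03)
  expect_gt(abs(top2$ei[1] - top2$ei[2]) / max(abs(top2$ei)), 0.20)

  # sweeping the coupling across the switch: the MIB changes and phi
  # jumps, while each fixed bipartition's ei moves continuously
  gs <- seq(0.30, 0.46, by = 0.02)
  results <- lapply(gs, function(g)
    phi_from_moments(stationary_moments(weaken(g), 1)))
  mibs <- vapply(results, function(r)
    paste(r$mib$part1, collapse = ","), character(1))
  phis <- vapply(results, function(r) r$value, numeric(1))
  switch_at <- which(mibs[-1] != mibs[-length(mibs)])
  expect_gte(length(switch_at), 1)
  i <- switch_at[1]
  expect_gt(abs(phis[i + 1] - phis[i]) / phis[i], 0.5)  # jump at the switch
  # per-bipartition ei continuity: max step change of any fixed bipartition
  ei_mat <- vapply(results, function(r) r$records$ei, numeric(127))
  expect_lt(max(abs(ei_mat[, i + 1] - ei_mat[, i])), 0.02)
})
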