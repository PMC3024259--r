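#' Independent-element surrogate for the maximum-entropy prior
#'
#' For stationary continuous Markovian systems there is no well-defined
#' maximum-entropy distribution on the real line; the surrogate replaces
#' it with the distribution in which each element is independent, Gaussian,
#' and carries its own stationary mean and variance. It is the prior over
#' initial states used by the Gaussian extension of the discrete/Markovian
#' integrated-information measure.
#'
#' @param model A stationary MVAR(1) [mvar_model()] (the extension is
#'   defined at a single step; `p != 1` is an error).
#' @return A list of class `surrogate_maxent` with `sigma` (diagonal
#'   matrix of stationary variances) and `n`.
#' @export
surrogate_maxent <- function(model) {
  stopifnot(inherits(model, "mvar_model"))
  if (model$p != 1)
    stop("the Gaussian extension is defined for MVAR(1) models only ",
         "(got p = ", model$p, ")", call. = FALSE)
  mom <- stationary_moments(model, tau = 1)
  structure(list(sigma = diag(diag(mom$sigma), model$n), n = model$n),
            class = "surrogate_maxent")
}

# posterior entropy H(X0 | X1) when X0 ~ N(0, prior), X1 = A X0 + eps:
# precision of X0 | X1 is prior^-1 + A' noise^-1 A  (Bayes' rule)
posterior_entropy <- function(A, noise_cov, prior) {
  d <- nrow(prior)
  prec <- chol2inv(chol(prior)) +
    t(A) %*% chol2inv(chol(noise_cov)) %*% A
  prec <- (prec + t(prec)) / 2
  0.5 * (d * log(2 * pi * exp(1)) - chol_logdet(prec, "posterior precision"))
}

#' Conditional entropy of the whole system under the surrogate prior
#'
#' \eqn{H(X_0 | X_1)} in nats, with \eqn{X_0} drawn from the
#' independent-element surrogate and \eqn{X_1 = A X_0 + \epsilon}.
#'
#' @inheritParams surrogate_maxent
#' @return Entropy in nats.
#' @export
conditional_entropy_whole <- function(model) {
  s <- surrogate_maxent(model)
  posterior_entropy(model$coeffs[[1]], model$noise_cov, s$sigma)
}

#' Conditional entropy of a sub-system under the surrogate prior
#'
#' \eqn{H(M_0 | M_1)} for a proper subset of elements, with states
#' external to the part carrying the surrogate distribution: the effective
#' noise of the part is its own noise plus the coupling-propagated
#' external surrogate variance,
#' \deqn{\Sigma'(\epsilon) = \Sigma(\epsilon)_{MM} +
#'   A_{M M^c}\,\Sigma^{max}_{M^c M^c}\,A_{M M^c}^\top.}
#'
#' @inheritParams surrogate_maxent
#' @param part Integer indices of the sub-system; a non-empty proper
#'   subset of `1:n`.
#' @return Entropy in nats.
#' @export
conditional_entropy_part <- function(model, part) {
  s <- surrogate_maxent(model)
  part <- sort(as.integer(part))
  if (length(part) == 0 || length(part) >= model$n ||
      any(part < 1 | part > model$n))
    stop("`part` must be a non-empty proper subset of 1:", model$n,
         call. = FALSE)
  comp <- setdiff(seq_len(model$n), part)
  A <- model$coeffs[[1]]
  A_mm <- A[part, part, drop = FALSE]
  A_mc <- A[part, comp, drop = FALSE]
  eff_noise <- model$noise_cov[part, part, drop = FALSE] +
    A_mc %*% s$sigma[comp, comp, drop = FALSE] %*% t(A_mc)
  posterior_entropy(A_mm, eff_noise, s$sigma[part, part, drop = FALSE])
}

#' Gaussian-extended expected integrated information (Phi-DM)
#'
#' The expected effective information of a bipartition under the
#' independent-element surrogate prior is
#' \eqn{\sum_k H(M^k_0 | M^k_1) - H(X_0 | X_1)}; the measure is its
#' non-normalized value at the bipartition minimizing the value normalized
#' by the smaller part's surrogate entropy. When the stationary covariance
#' is already diagonal the surrogate coincides with the stationary
#' distribution and the result equals Phi-E exactly.
#'
#' @inheritParams surrogate_maxent
#' @param eps_k Admissibility threshold for the normalization (nats).
#' @return A `phi_result` with `measure = "phi_dm"` and `tau = 1`.
#' @examples
#' phi_dm(make_network("uni_ring"))$value    # 0.0645, equal to Phi-E
#' phi_dm(make_network("recip_ring"))$value  # 0.1313
#' @export
phi_dm <- function(model, eps_k = 1e-6) {
  s <- surrogate_maxent(model)
  H_whole <- conditional_entropy_whole(model)
  bips <- enumerate_bipartitions(model$n)
  ei <- K <- numeric(length(bips))
  for (i in seq_along(bips)) {
    b <- bips[[i]]
    ei[i] <- conditional_entropy_part(model, b$part1) +
      conditional_entropy_part(model, b$part2) - H_whole
    K[i] <- min(
      gaussian_entropy(s$sigma[b$part1, b$part1, drop = FALSE]),
      gaussian_entropy(s$sigma[b$part2, b$part2, drop = FALSE]))
  }
  admissible <- K > eps_k
  if (!any(admissible))
    stop("all bipartitions inadmissible: surrogate normalization <= ",
         eps_k, call. = FALSE)
  normalized <- ifelse(admissible, ei / K, NA_real_)
  i_mib <- which(admissible)[which.min(normalized[admissible])]
  records <- tibble::tibble(
    part1 = vapply(bips, function(b) format_part(b$part1), character(1)),
    part2 = vapply(bips, function(b) format_part(b$part2), character(1)),
    ei = ei, K = K, normalized_ei = normalized, admissible = admissible,
    is_mib = seq_along(bips) == i_mib
  )
  new_phi_result("phi_dm", 1L, ei[i_mib], bips[[i_mib]], records,
                 list(source = "analytic", tau = 1L))
}
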