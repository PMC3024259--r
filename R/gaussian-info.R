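#' Partial covariance
#'
#' \deqn{\Sigma(X|Y) = \Sigma(X) - \Sigma(XY)\,\Sigma(Y)^{-1}\,\Sigma(XY)^\top.}
#' For jointly Gaussian variables this equals the covariance of the
#' conditional variable \eqn{X | Y = y} (for any y), and for any variables
#' it equals the residual covariance of the linear regression of X on Y.
#'
#' @param sigma_x Covariance of X.
#' @param sigma_xy Cross-covariance \eqn{Cov(X, Y)}.
#' @param sigma_y Covariance of Y; must be positive definite.
#' @return Symmetric positive semi-definite matrix.
#' @export
partial_covariance <- function(sigma_x, sigma_xy, sigma_y) {
  sigma_xy <- as.matrix(sigma_xy)
  R <- tryCatch(chol(sigma_y), error = function(e)
    stop("`sigma_y` is singular or not positive definite", call. = FALSE))
  # X - Sxy Sy^-1 Sxy' via triangular solves
  W <- backsolve(R, forwardsolve(t(R), t(sigma_xy)))
  out <- as.matrix(sigma_x) - sigma_xy %*% W
  (out + t(out)) / 2
}

# log-determinant via Cholesky; the error carries the caller's context
chol_logdet <- function(sigma, what = "covariance") {
  R <- tryCatch(chol(sigma), error = function(e)
    stop(what, " matrix is singular or not positive definite",
         call. = FALSE))
  2 * sum(log(diag(R)))
}

#' Differential entropy of a multivariate Gaussian (nats)
#'
#' \deqn{H = \tfrac12 \log\big((2\pi e)^d \det\Sigma\big)}
#' with the log-determinant computed via Cholesky. Negative values are
#' legal (differential entropy of small-variance continuous variables).
#'
#' @param sigma Symmetric positive-definite covariance matrix.
#' @return Entropy in nats.
#' @export
gaussian_entropy <- function(sigma) {
  sigma <- as.matrix(sigma)
  d <- nrow(sigma)
  0.5 * (d * log(2 * pi * exp(1)) + chol_logdet(sigma))
}

#' Gaussian mutual information between past and present (nats)
#'
#' \deqn{I(X_{t-\tau}; X_t) = \tfrac12 \log\frac{\det\Sigma(X)}
#'   {\det\Sigma(X_{t-\tau} | X_t)}.}
#' Tiny negative values from floating point (within -1e-10) are clipped
#' to zero.
#'
#' @param moments A `lagged_moments` object (see [stationary_moments()],
#'   [empirical_moments()]), or a stationary covariance matrix if
#'   `sigma_tau` is supplied.
#' @param sigma_tau Lagged auto-covariance \eqn{Cov(X_{t-\tau}, X_t)} when
#'   `moments` is given as a plain matrix.
#' @return Non-negative mutual information in nats.
#' @export
gaussian_mutual_information <- function(moments, sigma_tau = NULL) {
  if (inherits(moments, "lagged_moments")) {
    sigma <- moments$sigma; sigma_tau <- moments$sigma_tau
  } else {
    sigma <- as.matrix(moments)
    if (is.null(sigma_tau)) stop("`sigma_tau` required", call. = FALSE)
  }
  ld_sigma <- chol_logdet(sigma, "stationary covariance")
  cond <- partial_covariance(sigma, sigma_tau, sigma)
  ld_cond <- chol_logdet(cond, "conditional (joint near-singular)")
  mi <- 0.5 * (ld_sigma - ld_cond)
  if (mi < 0) {
    if (mi < -1e-10)
      warning("mutual information ", format(mi), " < 0; clipping to 0")
    mi <- 0
  }
  mi
}

# H(X_{t-tau} | X_t) in nats from stationary moments
gaussian_conditional_entropy <- function(sigma, sigma_tau) {
  gaussian_entropy(partial_covariance(sigma, sigma_tau, sigma))
}

#' Restrict stationary moments to a subset of elements
#'
#' Gaussian marginalization is sub-block extraction: the moments of a
#' sub-system are the rows/columns of the parent matrices at the subset
#' indices.
#'
#' @param moments A `lagged_moments` object.
#' @param idx Integer vector of element indices (1-based).
#' @return A `lagged_moments` object over the subset.
#' @export
moments_subset <- function(moments, idx) {
  stopifnot(inherits(moments, "lagged_moments"))
  structure(
    list(tau = moments$tau,
         sigma = moments$sigma[idx, idx, drop = FALSE],
         sigma_tau = moments$sigma_tau[idx, idx, drop = FALSE],
         n = length(idx), source = moments$source),
    class = "lagged_moments"
  )
}
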