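#' Estimate stationary and lagged covariances from multi-trial data
#'
#' Each trial is demeaned separately (trials are independent realizations),
#' then (past, present) pairs at lag `tau` are pooled across trials with no
#' cross-trial pairs. The stationary covariance is the symmetrized average
#' of the past-block and present-block estimates; normalization is the
#' unbiased 1/(T_effective - 1).
#'
#' @param data A [phi_ts()] object.
#' @param tau Positive integer lag; every trial must be longer than
#'   `tau + 1`.
#' @param jitter Optional non-negative diagonal inflation added to the
#'   stationary covariance estimate (default 0), for near-singular data.
#' @return A `lagged_moments` object with additional fields `T_effective`
#'   (total pooled pair count) and `trials`.
#' @export
empirical_moments <- function(data, tau = 1, jitter = 0) {
  stopifnot(inherits(data, "phi_ts"))
  if (tau < 1 || tau != round(tau))
    stop("`tau` must be a positive integer", call. = FALSE)
  tau <- as.integer(tau)
  if (data$T <= tau + 1)
    stop("trials of length ", data$T, " are too short for tau = ", tau,
         call. = FALSE)
  n <- data$n
  Cpp <- Cff <- Cpf <- matrix(0, n, n)
  T_eff <- 0L
  for (v in data$values) {
    vars <- apply(v, 2, stats::var)
    if (any(vars < 1e-12))
      stop("constant (zero-variance) channel(s): element ",
           paste(which(vars < 1e-12), collapse = ", "),
           "; covariance would be singular", call. = FALSE)
    vc <- sweep(v, 2, colMeans(v))
    Tt <- nrow(vc)
    past <- vc[1:(Tt - tau), , drop = FALSE]
    pres <- vc[(tau + 1):Tt, , drop = FALSE]
    Cpp <- Cpp + crossprod(past)
    Cff <- Cff + crossprod(pres)
    Cpf <- Cpf + crossprod(past, pres)
    T_eff <- T_eff + (Tt - tau)
  }
  norm <- T_eff - 1L
  sigma <- (Cpp + Cff) / (2 * norm)
  sigma <- (sigma + t(sigma)) / 2 + diag(jitter, n)
  structure(
    list(tau = as.integer(tau), sigma = sigma, sigma_tau = Cpf / norm,
         n = n, source = "empirical", T_effective = T_eff,
         trials = data$trials),
    class = "lagged_moments"
  )
}

#' Fit an MVAR(1) model to multi-trial time-series data
#'
#' Ordinary least squares of the present on the immediately preceding
#' state: \eqn{\hat A = \hat\Sigma(1)^\top \hat\Sigma^{-1}} and
#' \eqn{\hat\Sigma(\epsilon) = \hat\Sigma - \hat\Sigma(1)^\top
#' \hat\Sigma^{-1} \hat\Sigma(1)}, the partial covariance of the present
#' given the past (identical to the regression-residual covariance).
#'
#' @param data A [phi_ts()] object with `T > n + 2`.
#' @return A validated [mvar_model()]. If the estimated model is
#'   non-stationary (possible for short series), it is returned with a
#'   warning and `$stationary = FALSE`.
#' @examples
#' m <- mvar_model(matrix(0.5), matrix(1))
#' fit <- fit_mvar1(simulate_mvar(m, 2000, seed = 7))
#' fit$coeffs[[1]]  # close to 0.5
#' @export
fit_mvar1 <- function(data) {
  stopifnot(inherits(data, "phi_ts"))
  if (data$T <= data$n + 2)
    stop("need T > n + 2 time points to fit an MVAR(1)", call. = FALSE)
  mom <- empirical_moments(data, tau = 1)
  R <- tryCatch(chol(mom$sigma), error = function(e)
    stop("singular empirical covariance; cannot fit MVAR(1)", call. = FALSE))
  # A' = Sigma^-1 Sigma(1)  =>  A = Sigma(1)' Sigma^-1
  A <- t(backsolve(R, forwardsolve(t(R), mom$sigma_tau)))
  eps_cov <- partial_covariance(mom$sigma, t(mom$sigma_tau), mom$sigma)
  mvar_model(list(A), eps_cov, allow_nonstationary = TRUE)
}
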