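#' Construct a multivariate autoregressive (MVAR) generative model
#'
#' An MVAR(p) model describes the dynamics
#' \deqn{x_t = A_1 x_{t-1} + \dots + A_p x_{t-p} + \epsilon_t,}
#' where the \eqn{A_k} are generalized connectivity matrices acting at
#' different time lags (row = target element, column = source element) and
#' \eqn{\epsilon_t} is serially uncorrelated noise with covariance
#' `noise_cov`. This is the generative-model class underlying all analytic
#' integrated-information computations in this package.
#'
#' @param coeffs A square coefficient matrix, or a list of `p` square
#'   matrices of identical dimension, one per lag. Entry `[i, j]` of the
#'   k-th matrix is the influence of element `j` at lag `k` on element `i`.
#' @param noise_cov Symmetric positive-definite noise covariance matrix.
#'   Defaults to the identity.
#' @param allow_nonstationary If `TRUE`, a model whose companion matrix has
#'   spectral radius \eqn{\ge 1} is returned with a warning and flagged via
#'   `$stationary = FALSE` instead of raising an error. Needed only when
#'   working with models fitted from short or ill-conditioned data.
#'
#' @return An object of class `mvar_model`: a list with elements `n`
#'   (element count), `p` (model order), `coeffs` (list of `p` matrices),
#'   `noise_cov`, and `stationary` (logical).
#'
#' @examples
#' # univariate AR(1) with coefficient 0.5
#' m <- mvar_model(matrix(0.5), matrix(1))
#' spectral_radius(m)
#'
#' # an 8-element unidirectional ring, weight 0.25
#' ring <- make_network("uni_ring")
#' ring$p
#' @seealso [make_network()], [stationary_moments()], [simulate_mvar()]
#' @export
mvar_model <- function(coeffs, noise_cov = NULL, allow_nonstationary = FALSE) {
  if (is.matrix(coeffs)) coeffs <- list(coeffs)
  if (!is.list(coeffs) || length(coeffs) == 0L)
    stop("`coeffs` must be a matrix or a non-empty list of matrices",
         call. = FALSE)
  coeffs <- lapply(coeffs, function(A) {
    A <- as.matrix(A)
    storage.mode(A) <- "double"
    A
  })
  n <- nrow(coeffs[[1]])
  for (k in seq_along(coeffs)) {
    A <- coeffs[[k]]
    if (nrow(A) != n || ncol(A) != n)
      stop("coefficient matrix for lag ", k, " is not ", n, "x", n,
           call. = FALSE)
    if (anyNA(A)) stop("coefficient matrix for lag ", k, " contains NA",
                       call. = FALSE)
  }
  if (is.null(noise_cov)) noise_cov <- diag(n)
  noise_cov <- as.matrix(noise_cov)
  storage.mode(noise_cov) <- "double"
  if (nrow(noise_cov) != n || ncol(noise_cov) != n)
    stop("`noise_cov` must be ", n, "x", n, call. = FALSE)
  if (max(abs(noise_cov - t(noise_cov))) > 1e-10)
    stop("`noise_cov` is not symmetric", call. = FALSE)
  noise_cov <- (noise_cov + t(noise_cov)) / 2
  ok <- tryCatch({ chol(noise_cov); TRUE }, error = function(e) FALSE)
  if (!ok) stop("`noise_cov` is not positive definite", call. = FALSE)

  model <- structure(
    list(n = n, p = length(coeffs), coeffs = coeffs, noise_cov = noise_cov,
         stationary = TRUE),
    class = "mvar_model"
  )
  rho <- spectral_radius(model)
  if (rho >= 1 - 1e-9) {
    model$stationary <- FALSE
    msg <- sprintf(
      "model is not stationary: companion spectral radius %.6g >= 1", rho)
    if (!allow_nonstationary) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  model
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("<mvar_model> MVAR(%d), %d elements, spectral radius %.4f%s\n",
              x$p, x$n, spectral_radius(x),
              if (x$stationary) "" else " [non-stationary]"))
  invisible(x)
}

#' Spectral radius of the companion matrix of an MVAR model
#'
#' The model is stationary iff the result is below 1 (equivalently, all
#' roots of the lag polynomial lie outside the unit circle).
#'
#' @param model An [mvar_model()].
#' @return Non-negative scalar: the largest eigenvalue modulus of the
#'   block-companion matrix.
#' @export
spectral_radius <- function(model) {
  stopifnot(inherits(model, "mvar_model"))
  big <- companion_blocks(model$coeffs, model$n, model$p, r = model$p)
  max(Mod(eigen(big, only.values = TRUE)$values))
}

# rn x rn block-companion matrix: coefficient blocks in the first block row
# (zeros beyond lag p), identity blocks on the first sub-block-diagonal.
companion_blocks <- function(coeffs, n, p, r) {
  big <- matrix(0, r * n, r * n)
  for (k in seq_len(p)) big[1:n, ((k - 1) * n + 1):(k * n)] <- coeffs[[k]]
  if (r > 1) {
    idx <- seq_len((r - 1) * n)
    big[cbind(n + idx, idx)] <- 1
  }
  big
}

#' Block-companion embedding of an MVAR(p) model
#'
#' Rewrites an MVAR(p) process as an equivalent MVAR(1) process on the
#' stacked state \eqn{(x_t, x_{t-1}, \dots, x_{t-r+1})}. Used internally to
#' obtain stationary moments for any order and lag from a single
#' discrete-time Lyapunov equation.
#'
#' @param model An [mvar_model()].
#' @param r Embedding order, at least `model$p`. Blocks for lags beyond `p`
#'   are zero.
#' @return A list of class `companion_form` with elements `r`, `big_coeff`
#'   (the \eqn{rn \times rn} companion matrix) and `big_noise_cov`
#'   (noise covariance in the top-left block, zeros elsewhere).
#' @export
companion <- function(model, r = model$p) {
  stopifnot(inherits(model, "mvar_model"))
  if (r < model$p)
    stop("embedding order r = ", r, " is below the model order p = ",
         model$p, call. = FALSE)
  n <- model$n
  bigQ <- matrix(0, r * n, r * n)
  bigQ[1:n, 1:n] <- model$noise_cov
  structure(
    list(r = r,
         big_coeff = companion_blocks(model$coeffs, n, model$p, r),
         big_noise_cov = bigQ),
    class = "companion_form"
  )
}

# Solve the discrete-time Lyapunov equation S = A S A' + Q by
# vectorization: (I - A (x) A) vec(S) = vec(Q).
dlyap_solve <- function(A, Q) {
  m <- nrow(A)
  S <- matrix(solve(diag(m * m) - kronecker(A, A), as.vector(Q)), m, m)
  (S + t(S)) / 2
}

#' Analytic stationary and lagged moments of an MVAR model
#'
#' Solves the discrete-time Lyapunov equation
#' \eqn{\tilde\Sigma = \tilde A \tilde\Sigma \tilde A^\top + \tilde\Sigma(\epsilon)}
#' for the companion embedding and reads off the stationary covariance
#' \eqn{\Sigma(X)} and the lag-\eqn{\tau} auto-covariance
#' \eqn{\Sigma(X_{t-\tau}, X_t)} (past indexes rows). Lags beyond the
#' companion order are filled in by the Yule-Walker recursion
#' \eqn{\Gamma_j = \sum_k \Gamma_{j-k} A_k^\top}.
#'
#' @param model A stationary [mvar_model()].
#' @param tau Positive integer lag (time steps).
#' @return An object of class `lagged_moments`: list with `tau`, `sigma`
#'   (\eqn{\Sigma(X)}), `sigma_tau` (\eqn{\Sigma(X_{t-\tau}, X_t)}), `n`,
#'   and `source = "analytic"`.
#' @examples
#' m <- mvar_model(matrix(0.5), matrix(1))
#' mom <- stationary_moments(m, tau = 1)
#' mom$sigma      # 1/(1 - 0.25) = 4/3
#' mom$sigma_tau  # 0.5 * 4/3 = 2/3
#' @export
stationary_moments <- function(model, tau = 1) {
  stopifnot(inherits(model, "mvar_model"))
  if (!model$stationary)
    stop("stationary moments are undefined for a non-stationary model",
         call. = FALSE)
  if (tau < 1 || tau != round(tau)) stop("`tau` must be a positive integer",
                                         call. = FALSE)
  n <- model$n
  cf <- companion(model)
  S_big <- dlyap_solve(cf$big_coeff, cf$big_noise_cov)
  resid <- cf$big_coeff %*% S_big %*% t(cf$big_coeff) + cf$big_noise_cov - S_big
  if (norm(resid, "F") > 1e-8 * max(norm(S_big, "F"), 1))
    stop("Lyapunov solution failed the fixed-point residual check",
         call. = FALSE)
  # Gamma_j = Cov(X_{t-j}, X_t); blocks (j+1, 1) of the companion solution
  gam <- vector("list", max(tau, model$p) + 1L)
  for (j in 0:(cf$r - 1L))
    gam[[j + 1L]] <- S_big[(j * n + 1):((j + 1) * n), 1:n, drop = FALSE]
  if (tau > cf$r - 1L) {
    for (j in cf$r:tau) {
      G <- matrix(0, n, n)
      for (k in seq_len(model$p)) {
        d <- j - k
        Gd <- if (d >= 0) gam[[d + 1L]] else t(gam[[-d + 1L]])
        G <- G + Gd %*% t(model$coeffs[[k]])
      }
      gam[[j + 1L]] <- G
    }
  }
  sigma <- (gam[[1L]] + t(gam[[1L]])) / 2
  structure(
    list(tau = as.integer(tau), sigma = sigma, sigma_tau = gam[[tau + 1L]],
         n = n, source = "analytic"),
    class = "lagged_moments"
  )
}

#' @export
print.lagged_moments <- function(x, ...) {
  cat(sprintf("<lagged_moments> %d elements, tau = %d (%s)\n",
              x$n, x$tau, x$source))
  invisible(x)
}
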