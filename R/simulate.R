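#' Specify an innovation (noise) distribution for simulation
#'
#' @param family `"gaussian"` (multivariate normal with covariance
#'   `covariance`, defaulting to the model's `noise_cov`) or
#'   `"exponential"` (independent exponential innovations with mean and
#'   variance 1 per element; not centered — downstream moment estimation
#'   demeans, so covariances are unaffected). The exponential family
#'   emulates the aggregate activity of Poissonian spiking populations.
#' @param covariance Optional covariance matrix for the Gaussian family.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(family = c("gaussian", "exponential"),
                       covariance = NULL) {
  family <- match.arg(family)
  if (family == "exponential" && !is.null(covariance))
    stop("exponential innovations are independent with unit variance; ",
         "`covariance` must not be supplied", call. = FALSE)
  structure(list(family = family, covariance = covariance),
            class = "noise_spec")
}

#' Simulate multi-trial time series from an MVAR model
#'
#' Iterates \eqn{x_t = \sum_k A_k x_{t-k} + \epsilon_t} from a zero initial
#' history, discards `burn_in` initial samples per trial, and returns
#' `trials` independent realizations. Fully deterministic given `seed`.
#'
#' @param model A stationary [mvar_model()].
#' @param T_points Post-burn-in time points per trial.
#' @param trials Number of independent trials.
#' @param noise A [noise_spec()]; defaults to Gaussian with the model's
#'   noise covariance.
#' @param burn_in Samples discarded before recording starts (default 1000).
#' @param seed Integer seed; all randomness flows from it.
#' @return A `phi_ts` object: list with `values` (list of `T_points` x `n`
#'   matrices, one per trial), `trials`, `T`, `n`, `seed`, `noise_family`.
#' @examples
#' net <- make_network("recip_ring")
#' ts <- simulate_mvar(net, T_points = 500, trials = 2, seed = 1)
#' dim(ts$values[[1]])
#' @export
simulate_mvar <- function(model, T_points, trials = 1,
                          noise = noise_spec("gaussian"),
                          burn_in = 1000, seed = NULL) {
  stopifnot(inherits(model, "mvar_model"), inherits(noise, "noise_spec"))
  if (!model$stationary)
    stop("refusing to simulate a non-stationary model", call. = FALSE)
  if (T_points < 1 || trials < 1)
    stop("`T_points` and `trials` must be positive", call. = FALSE)
  n <- model$n; p <- model$p
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  chol_noise <- if (noise$family == "gaussian") {
    cv <- if (is.null(noise$covariance)) model$noise_cov else as.matrix(noise$covariance)
    t(chol(cv))
  } else NULL
  total <- burn_in + T_points
  out <- vector("list", trials)
  for (tr in seq_len(trials)) {
    eps <- if (noise$family == "gaussian") {
      matrix(stats::rnorm(total * n), n, total)
    } else {
      matrix(stats::rexp(total * n, rate = 1), n, total)
    }
    if (!is.null(chol_noise)) eps <- chol_noise %*% eps
    x <- matrix(0, n, total + p)  # p columns of zero initial history
    for (t in seq_len(total)) {
      acc <- eps[, t]
      for (k in seq_len(p)) acc <- acc + model$coeffs[[k]] %*% x[, t + p - k]
      x[, t + p] <- acc
    }
    out[[tr]] <- t(x[, (p + burn_in + 1):(p + total), drop = FALSE])
  }
  phi_ts(out, seed = seed, noise_family = noise$family)
}

#' Assemble multi-trial time-series data
#'
#' @param values A list of numeric matrices (rows = time, columns =
#'   elements), one per trial; all trials must share dimensions, with no
#'   missing values.
#' @param seed,noise_family Optional provenance metadata.
#' @return A `phi_ts` object.
#' @export
phi_ts <- function(values, seed = NULL, noise_family = NULL) {
  if (is.matrix(values)) values <- list(values)
  stopifnot(is.list(values), length(values) >= 1)
  values <- lapply(values, as.matrix)
  d <- dim(values[[1]])
  for (v in values) {
    if (!identical(dim(v), d))
      stop("all trials must have identical dimensions", call. = FALSE)
    if (anyNA(v)) stop("time series contains missing values", call. = FALSE)
  }
  structure(
    list(values = values, trials = length(values), T = d[1], n = d[2],
         seed = seed, noise_family = noise_family),
    class = "phi_ts"
  )
}

#' @export
print.phi_ts <- function(x, ...) {
  cat(sprintf("<phi_ts> %d trial(s) x %d time points x %d elements\n",
              x$trials, x$T, x$n))
  invisible(x)
}

#' @describeIn phi_ts Long-format view: one row per (trial, time, element).
#' @param x A `phi_ts` object.
#' @param ... Unused.
#' @exportS3Method tibble::as_tibble
as_tibble.phi_ts <- function(x, ...) {
  purrr::map_dfr(seq_len(x$trials), function(tr) {
    v <- x$values[[tr]]
    tibble::tibble(
      trial = tr,
      time = rep(seq_len(nrow(v)), ncol(v)),
      element = rep(seq_len(ncol(v)), each = nrow(v)),
      value = as.vector(v)
    )
  })
}
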