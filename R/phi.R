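#' Effective information across a bipartition (nats)
#'
#' The mutual information between past and present generated by the whole
#' system minus the sum generated by the two parts considered
#' independently:
#' \deqn{\varphi(B, \tau) = I(X_{t-\tau}; X_t) - \sum_{k=1,2}
#'   I(M^k_{t-\tau}; M^k_t).}
#' May be negative for redundancy-dominated systems; it is reported as-is.
#'
#' @param moments A `lagged_moments` object for the whole system.
#' @param bipartition A `bipartition` (see [enumerate_bipartitions()]), or
#'   a list with integer fields `part1` and `part2`.
#' @return Effective information in nats.
#' @export
effective_information <- function(moments, bipartition) {
  stopifnot(inherits(moments, "lagged_moments"))
  gaussian_mutual_information(moments) -
    gaussian_mutual_information(moments_subset(moments, bipartition$part1)) -
    gaussian_mutual_information(moments_subset(moments, bipartition$part2))
}

#' Normalization factor K for the bipartition search (nats)
#'
#' The smaller of the two parts' stationary Gaussian entropies. Normalizing
#' effective information by K biases the minimum-information-bipartition
#' search toward parts of roughly equal size; without it the search would
#' trivially favor single-element splits.
#'
#' @inheritParams effective_information
#' @return Positive scalar in nats.
#' @export
normalization_K <- function(moments, bipartition) {
  stopifnot(inherits(moments, "lagged_moments"))
  min(gaussian_entropy(moments$sigma[bipartition$part1, bipartition$part1,
                                     drop = FALSE]),
      gaussian_entropy(moments$sigma[bipartition$part2, bipartition$part2,
                                     drop = FALSE]))
}

#' Stochastic interaction across a bipartition (nats)
#'
#' The conditional-entropy analogue of effective information:
#' \deqn{\sum_{k=1,2} H(M^k_{t-\tau} | M^k_t) - H(X_{t-\tau} | X_t).}
#'
#' @inheritParams effective_information
#' @return Stochastic interaction in nats.
#' @export
stochastic_interaction <- function(moments, bipartition) {
  stopifnot(inherits(moments, "lagged_moments"))
  ce <- function(idx) {
    m <- moments_subset(moments, idx)
    gaussian_conditional_entropy(m$sigma, m$sigma_tau)
  }
  ce(bipartition$part1) + ce(bipartition$part2) -
    gaussian_conditional_entropy(moments$sigma, moments$sigma_tau)
}

new_phi_result <- function(measure, tau, value, mib, records, provenance) {
  structure(
    list(measure = measure, tau = tau, value = value, mib = mib,
         records = records, provenance = provenance),
    class = "phi_result"
  )
}

#' Integrated information from stationary moments
#'
#' Evaluates effective information (or stochastic interaction for
#' `phi_e_tilde`) and the normalization K over every bipartition; the
#' minimum information bipartition (MIB) is the admissible bipartition
#' (K above `eps_k`) minimizing normalized effective information, with
#' ties broken by smaller `part1` then enumeration order. The measure's
#' value is the *non-normalized* effective information at the MIB.
#'
#' `phi_ar` is numerically identical to `phi_e` on the same covariance
#' inputs — residual covariance of the linear regression of past on
#' present equals the partial covariance — and differs only in
#' interpretation (prediction error rather than Shannon information);
#' the label records which reading is intended.
#'
#' @param moments A `lagged_moments` object (analytic or empirical).
#' @param measure One of `"phi_e"`, `"phi_e_tilde"`, `"phi_ar"`.
#' @param eps_k Admissibility threshold for K (nats); bipartitions with
#'   `K <= eps_k` are excluded from the MIB search and flagged in the
#'   record table.
#' @return A `phi_result`: measure label, `tau`, `value` (nats), `mib`
#'   (the bipartition), `records` (tibble with one row per bipartition:
#'   parts, `ei`, `K`, `normalized_ei`, `admissible`) and provenance.
#' @examples
#' net <- make_network("uni_ring")
#' phi_from_moments(stationary_moments(net, 1))$value  # 0.0645
#' @export
phi_from_moments <- function(moments,
                             measure = c("phi_e", "phi_e_tilde", "phi_ar"),
                             eps_k = 1e-6) {
  stopifnot(inherits(moments, "lagged_moments"))
  measure <- match.arg(measure)
  if (moments$n < 2)
    stop("integrated information needs at least 2 elements", call. = FALSE)
  bips <- enumerate_bipartitions(moments$n)
  fun <- if (measure == "phi_e_tilde") stochastic_interaction
         else effective_information
  ei <- K <- numeric(length(bips))
  for (i in seq_along(bips)) {
    ei[i] <- fun(moments, bips[[i]])
    K[i] <- normalization_K(moments, bips[[i]])
  }
  admissible <- K > eps_k
  if (!any(admissible))
    stop("all bipartitions inadmissible: normalization K <= ", eps_k,
         " for every split (offending: all ", length(bips), ")",
         call. = FALSE)
  normalized <- ifelse(admissible, ei / K, NA_real_)
  # enumeration is ordered by |part1| then lexicographic, so the first
  # minimum implements the documented tie-break
  i_mib <- which(admissible)[which.min(normalized[admissible])]
  records <- tibble::tibble(
    part1 = vapply(bips, function(b) format_part(b$part1), character(1)),
    part2 = vapply(bips, function(b) format_part(b$part2), character(1)),
    ei = ei, K = K, normalized_ei = normalized, admissible = admissible,
    is_mib = seq_along(bips) == i_mib
  )
  prov <- list(source = moments$source, tau = moments$tau)
  if (!is.null(moments$T_effective)) {
    prov$T_effective <- moments$T_effective
    prov$trials <- moments$trials
  }
  new_phi_result(measure, moments$tau, ei[i_mib], bips[[i_mib]], records,
                 prov)
}

#' Analytic integrated information of an MVAR model
#'
#' Exact up to linear-algebra tolerance: stationary moments come from the
#' discrete-time Lyapunov equation, with no simulation.
#'
#' @param model A stationary [mvar_model()].
#' @param tau Lag (time steps) at which information is measured.
#' @inheritParams phi_from_moments
#' @return A `phi_result`.
#' @examples
#' phi_analytic(make_network("chain"))$value       # 0.0323
#' phi_analytic(make_network("recip_ring"))$value  # 0.1283
#' @export
phi_analytic <- function(model, tau = 1,
                         measure = c("phi_e", "phi_e_tilde", "phi_ar"),
                         eps_k = 1e-6) {
  measure <- match.arg(measure)
  res <- phi_from_moments(stationary_moments(model, tau), measure, eps_k)
  res$provenance$source <- "analytic"
  res
}

#' Empirical integrated information from multi-trial time series
#'
#' @param data A [phi_ts()] object.
#' @param tau Lag (time steps).
#' @inheritParams phi_from_moments
#' @param mode `"per_trial"` (default): one `phi_result` per trial plus a
#'   mean/sd/coefficient-of-variation summary — the reporting convention
#'   for multi-trial stability experiments. `"pooled"`: a single result
#'   from covariances pooled across trials.
#' @return For `"pooled"`, a `phi_result`. For `"per_trial"`, a
#'   `phi_result_set`: list with `results` (per-trial `phi_result`s) and
#'   `summary` (one-row tibble: mean, sd, cv, trials).
#' @export
phi_empirical <- function(data, tau = 1,
                          measure = c("phi_e", "phi_e_tilde", "phi_ar"),
                          mode = c("per_trial", "pooled"), eps_k = 1e-6) {
  stopifnot(inherits(data, "phi_ts"))
  measure <- match.arg(measure)
  mode <- match.arg(mode)
  if (mode == "pooled") {
    res <- phi_from_moments(empirical_moments(data, tau), measure, eps_k)
    res$provenance$seed <- data$seed
    return(res)
  }
  results <- lapply(seq_len(data$trials), function(tr) {
    one <- phi_ts(data$values[tr], seed = data$seed)
    r <- phi_from_moments(empirical_moments(one, tau), measure, eps_k)
    r$provenance$trial <- tr
    r
  })
  vals <- vapply(results, function(r) r$value, numeric(1))
  structure(
    list(results = results,
         values = vals,
         summary = tibble::tibble(
           measure = measure, tau = tau, trials = data$trials,
           mean = mean(vals), sd = stats::sd(vals),
           cv = stats::sd(vals) / mean(vals))),
    class = "phi_result_set"
  )
}

#' @export
print.phi_result <- function(x, ...) {
  cat(sprintf("<phi_result> %s(tau=%d) = %.6f nats\n", x$measure, x$tau,
              x$value))
  cat(sprintf("  MIB: {%s} | {%s}   (%d bipartitions searched, %s)\n",
              format_part(x$mib$part1), format_part(x$mib$part2),
              nrow(x$records), x$provenance$source))
  invisible(x)
}

#' @export
print.phi_result_set <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<phi_result_set> %s(tau=%d), %d trials: mean %.4f, sd %.4f, cv %.3f\n",
    s$measure, s$tau, s$trials, s$mean, s$sd, s$cv))
  invisible(x)
}

# ---- fast value-only evaluator (used by the genetic algorithm) ----------
#
# parts: list of integer index vectors (part1 per bipartition; part2 is the
# complement), precomputed once per n. Returns the non-normalized ei at the
# MIB for an MVAR(1) coefficient matrix with the given noise covariance.
phi_e_value_fast <- function(A, noise_cov, parts_env) {
  n <- nrow(A)
  S <- dlyap_solve(A, noise_cov)
  St <- S %*% t(A)
  J <- rbind(cbind(S, St), cbind(t(St), S))
  ld_S <- 2 * sum(log(diag(chol(S))))
  ld_J <- 2 * sum(log(diag(chol(J))))
  mi_whole <- 0.5 * (2 * ld_S - ld_J)
  half_l2pe <- 0.5 * log(2 * pi * exp(1))
  nb <- length(parts_env$p1)
  best_nei <- Inf; best_ei <- NA_real_
  sub_stats <- function(idx) {
    Sp <- S[idx, idx, drop = FALSE]
    Jp <- J[c(idx, idx + n), c(idx, idx + n), drop = FALSE]
    ld_sp <- 2 * sum(log(diag(chol(Sp))))
    ld_jp <- 2 * sum(log(diag(chol(Jp))))
    c(mi = 0.5 * (2 * ld_sp - ld_jp),
      H = length(idx) * half_l2pe + 0.5 * ld_sp)
  }
  for (i in seq_len(nb)) {
    s1 <- sub_stats(parts_env$p1[[i]])
    s2 <- sub_stats(parts_env$p2[[i]])
    ei <- mi_whole - s1[["mi"]] - s2[["mi"]]
    K <- min(s1[["H"]], s2[["H"]])
    if (K > 1e-6) {
      nei <- ei / K
      if (nei < best_nei) { best_nei <- nei; best_ei <- ei }
    }
  }
  best_ei
}

bipartition_index_cache <- new.env(parent = emptyenv())

parts_for_n <- function(n) {
  key <- as.character(n)
  if (is.null(bipartition_index_cache[[key]])) {
    bips <- enumerate_bipartitions(n)
    bipartition_index_cache[[key]] <- list(
      p1 = lapply(bips, `[[`, "part1"),
      p2 = lapply(bips, `[[`, "part2"))
  }
  bipartition_index_cache[[key]]
}
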