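#' Canonical connectivity generators
#'
#' Builds the MVAR(1) models of the canonical 8-element examples, all with
#' identity noise covariance unless overridden:
#'
#' * `chain` — a non-closed chain of `n - 1` unidirectional links of
#'   strength `weight` (element i feeds element i + 1).
#' * `uni_ring` — a closed unidirectional ring, `n` links.
#' * `recip_ring` — a ring of reciprocal connections, `2n` directed links.
#' * `homogeneous` — all-to-all with every off-diagonal entry
#'   `1/(2(n-1))`, so the total afference of every element is 0.5.
#' * `shortcut_ring` — a reciprocal ring plus directed long-range
#'   shortcuts given as a two-column (from, to) matrix.
#' * `custom` — an explicit coefficient matrix via `coeffs`.
#'
#' @param kind Network kind; see above.
#' @param n Number of elements (default 8).
#' @param weight Connection strength for link-based kinds (default 0.25).
#' @param shortcuts Two-column integer matrix of (source, target) pairs for
#'   `shortcut_ring`.
#' @param coeffs Coefficient matrix for `custom`.
#' @param noise_cov Noise covariance (default identity).
#' @return A stationary [mvar_model()].
#' @examples
#' sum(make_network("chain")$coeffs[[1]] != 0)        # 7 links
#' sum(make_network("homogeneous")$coeffs[[1]] != 0)  # 56 links of 1/14
#' @export
make_network <- function(kind = c("chain", "uni_ring", "recip_ring",
                                  "homogeneous", "shortcut_ring", "custom"),
                         n = 8, weight = 0.25, shortcuts = NULL,
                         coeffs = NULL, noise_cov = NULL) {
  kind <- match.arg(kind)
  A <- matrix(0, n, n)
  next_in_ring <- function(i) i %% n + 1L
  if (kind == "chain") {
    for (i in seq_len(n - 1)) A[i + 1, i] <- weight
  } else if (kind == "uni_ring") {
    for (i in seq_len(n)) A[next_in_ring(i), i] <- weight
  } else if (kind %in% c("recip_ring", "shortcut_ring")) {
    for (i in seq_len(n)) {
      A[next_in_ring(i), i] <- weight
      A[i, next_in_ring(i)] <- weight
    }
    if (kind == "shortcut_ring") {
      if (is.null(shortcuts))
        stop("`shortcuts` (from, to pairs) required for shortcut_ring",
             call. = FALSE)
      shortcuts <- matrix(as.integer(shortcuts), ncol = 2)
      for (j in seq_len(nrow(shortcuts))) {
        if (shortcuts[j, 1] == shortcuts[j, 2])
          stop("self-connections are not allowed", call. = FALSE)
        A[shortcuts[j, 2], shortcuts[j, 1]] <- weight
      }
    }
  } else if (kind == "homogeneous") {
    A[] <- 1 / (2 * (n - 1))
    diag(A) <- 0
  } else { # custom
    if (is.null(coeffs)) stop("`coeffs` required for kind = \"custom\"",
                              call. = FALSE)
    A <- as.matrix(coeffs)
  }
  mvar_model(list(A), noise_cov %||% diag(n))
}
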