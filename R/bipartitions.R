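#' Enumerate all bipartitions of n elements
#'
#' A bipartition splits `{1, ..., n}` into two disjoint, jointly exhaustive,
#' non-empty parts. In canonical form element 1 belongs to `part1` and
#' `part1` is sorted; there are \eqn{2^{n-1} - 1} distinct bipartitions.
#' The order is deterministic: by size of `part1`, then lexicographic.
#'
#' @param n Number of elements (at least 2). Exhaustive enumeration is
#'   refused above `max_n` (default 20, about 5e5 bipartitions) unless the
#'   cap is raised explicitly.
#' @param max_n Guard against combinatorial explosion.
#' @return A list of `bipartition` objects, each a list with sorted integer
#'   vectors `part1` and `part2`.
#' @examples
#' length(enumerate_bipartitions(4))  # 7
#' enumerate_bipartitions(3)[[1]]
#' @export
enumerate_bipartitions <- function(n, max_n = 20) {
  if (n < 2) stop("need at least 2 elements to bipartition", call. = FALSE)
  if (n > max_n)
    stop("exhaustive enumeration of 2^(", n, "-1)-1 bipartitions refused; ",
         "raise `max_n` explicitly if this is intended", call. = FALSE)
  out <- vector("list", 2^(n - 1) - 1)
  pos <- 0L
  rest <- if (n > 1) 2:n else integer(0)
  for (s in 1:(n - 1)) {          # |part1| = s, always contains element 1
    extra <- s - 1L
    combs <- if (extra == 0L) matrix(integer(0), nrow = 0, ncol = 1)
             else utils::combn(rest, extra)
    for (j in seq_len(ncol(combs))) {
      p1 <- c(1L, combs[, j])
      pos <- pos + 1L
      out[[pos]] <- structure(
        list(part1 = as.integer(p1),
             part2 = setdiff(seq_len(n), p1)),
        class = "bipartition"
      )
    }
  }
  out
}

#' @export
print.bipartition <- function(x, ...) {
  cat(sprintf("{%s} | {%s}\n", paste(x$part1, collapse = ","),
              paste(x$part2, collapse = ",")))
  invisible(x)
}

format_part <- function(idx) paste(idx, collapse = ",")
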