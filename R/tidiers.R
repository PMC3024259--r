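#' Tidy the per-bipartition record table of a result
#'
#' @param x A `phi_result`.
#' @param ... Unused.
#' @return A tibble with one row per bipartition: `part1`, `part2`, `ei`,
#'   `K`, `normalized_ei`, `admissible`, `is_mib`.
#' @exportS3Method generics::tidy
tidy.phi_result <- function(x, ...) x$records

#' One-row summary of a result
#'
#' @param x A `phi_result`.
#' @param ... Unused.
#' @return A one-row tibble: `measure`, `tau`, `value`, `mib_part1`,
#'   `mib_part2`, `n_bipartitions`.
#' @exportS3Method generics::glance
glance.phi_result <- function(x, ...) {
  tibble::tibble(
    measure = x$measure, tau = x$tau, value = x$value,
    mib_part1 = format_part(x$mib$part1),
    mib_part2 = format_part(x$mib$part2),
    n_bipartitions = nrow(x$records))
}

#' Per-trial values of a multi-trial result set
#'
#' @param x A `phi_result_set` from [phi_empirical()].
#' @param ... Unused.
#' @return A tibble with one row per trial: `trial`, `value`, `mib_part1`,
#'   `mib_part2`.
#' @exportS3Method generics::tidy
tidy.phi_result_set <- function(x, ...) {
  tibble::tibble(
    trial = seq_along(x$results),
    value = x$values,
    mib_part1 = vapply(x$results, function(r) format_part(r$mib$part1),
                       character(1)),
    mib_part2 = vapply(x$results, function(r) format_part(r$mib$part2),
                       character(1)))
}

#' @rdname tidy.phi_result_set
#' @exportS3Method generics::glance
glance.phi_result_set <- function(x, ...) x$summary

#' Plot the bipartition landscape of a result
#'
#' Normalized effective information for every bipartition, ordered as
#' enumerated (by size of part 1, then lexicographic), with the minimum
#' information bipartition highlighted.
#'
#' @param object A `phi_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.phi_result <- function(object, ...) {
  d <- object$records
  d$index <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = .data$normalized_ei)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_mib), size = 1.5,
                        na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "bipartition (enumeration order)",
                  y = "normalized effective information (nats)",
                  title = sprintf("%s(tau=%d) = %.4f at MIB {%s}|{%s}",
                                  object$measure, object$tau, object$value,
                                  format_part(object$mib$part1),
                                  format_part(object$mib$part2))) +
    ggplot2::theme_minimal()
}

#' Plot a genetic-algorithm fitness history
#'
#' @param object A `phi_evolution` from [evolve_networks()].
#' @param ... Unused.
#' @return A ggplot object showing best-so-far and population-mean Phi-E
#'   per generation.
#' @exportS3Method ggplot2::autoplot
autoplot.phi_evolution <- function(object, ...) {
  h <- object$history
  ggplot2::ggplot(h, ggplot2::aes(x = .data$generation)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$best), colour = "red") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "grey40") +
    ggplot2::labs(x = "generation", y = "Phi-E (nats)",
                  title = sprintf("GA condition '%s': best %.4f",
                                  object$condition, object$best_phi)) +
    ggplot2::theme_minimal()
}

#' Plot a connection-strength sweep
#'
#' Phi-E along the swept weight grid, with vertical marks where the
#' minimum information bipartition switches (the points at which Phi-E can
#' jump discontinuously).
#'
#' @param object A `phi_sweep` from [connection_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.phi_sweep <- function(object, ...) {
  switches <- object$weight[which(object$mib_changed)]
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$weight, y = .data$phi)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 0.8, na.rm = TRUE) +
    ggplot2::labs(x = "connection strength", y = "Phi-E (nats)") +
    ggplot2::theme_minimal()
  if (length(switches) > 0)
    p <- p + ggplot2::geom_vline(xintercept = switches, linetype = "dashed",
                                 colour = "red")
  p
}
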