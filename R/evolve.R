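#' Genetic-algorithm optimization of network topology for high Phi-E
#'
#' Evolves MVAR(1) connectivity matrices with analytic Phi-E (at lag
#' `tau`) as the fitness, under one of two constraint regimes:
#'
#' * `"fixed"` — every element receives exactly 2 afferents of strength
#'   0.25; mutation rearranges 2 connections (removes two existing links
#'   and adds replacements in the same rows, preserving the constraint).
#' * `"vary"` — the total afference of every element is 0.5, with all
#'   afferents to a given element equal and positive; initialization gives
#'   each element on average 2 afferents; mutation (with equal
#'   probability) adds, removes, or swaps 2 connections, followed by
#'   renormalization of each row.
#'
#' Selection is rank-based with replacement (probability proportional to
#' fitness rank) and one elite individual is copied unmutated per
#' generation, so best-so-far fitness is non-decreasing. Mutants that
#' violate stationarity are rejected and re-mutated (rare: row sums of at
#' most 0.5 keep the spectral radius at or below 0.5). The run is fully
#' deterministic given `seed`.
#'
#' @param condition `"fixed"` or `"vary"`.
#' @param population Individuals per generation (default 30).
#' @param generations Number of generations (default 200, allowing fitness
#'   to asymptote).
#' @param seed Integer seed for the whole run.
#' @param n Elements per network (default 8).
#' @param tau Fitness lag (default 1).
#' @return A list of class `phi_evolution`: `best_model` (an
#'   [mvar_model()]), `best_phi`, `history` (tibble: generation, best,
#'   mean, sd), `final_fitness` (numeric vector over the last population),
#'   `condition`, `seed`.
#' @export
evolve_networks <- function(condition = c("fixed", "vary"), population = 30,
                            generations = 200, seed = 1, n = 8, tau = 1) {
  condition <- match.arg(condition)
  if (population < 2) stop("`population` must be at least 2", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  parts <- parts_for_n(n)
  noise <- diag(n)
  fitness <- function(A) {
    if (tau == 1) return(phi_e_value_fast(A, noise, parts))
    m <- mvar_model(list(A), noise)
    phi_analytic(m, tau = tau)$value
  }
  pop <- replicate(population, init_individual(condition, n),
                   simplify = FALSE)
  fit <- vapply(pop, fitness, numeric(1))
  best_A <- pop[[which.max(fit)]]
  best_phi <- max(fit)
  hist <- vector("list", generations)
  for (g in seq_len(generations)) {
    ord <- order(fit, decreasing = TRUE)
    # rank-based selection: weight population - rank + 1, best ranked first
    w <- rev(seq_len(population))
    offspring <- vector("list", population)
    offspring[[1]] <- pop[[ord[1]]]  # elite, unmutated
    for (i in 2:population) {
      parent <- pop[[ord[sample.int(population, 1, prob = w)]]]
      offspring[[i]] <- mutate_individual(parent, condition, n)
    }
    pop <- offspring
    fit <- vapply(pop, fitness, numeric(1))
    if (max(fit) > best_phi) {
      best_phi <- max(fit)
      best_A <- pop[[which.max(fit)]]
    }
    hist[[g]] <- tibble::tibble(generation = g, best = best_phi,
                                mean = mean(fit), sd = stats::sd(fit))
  }
  structure(
    list(best_model = mvar_model(list(best_A), noise),
         best_phi = best_phi,
         history = dplyr::bind_rows(hist),
         final_fitness = fit,
         condition = condition, seed = seed),
    class = "phi_evolution"
  )
}

#' @export
print.phi_evolution <- function(x, ...) {
  cat(sprintf(
    "<phi_evolution> condition '%s', %d generations: best Phi-E = %.4f\n",
    x$condition, max(x$history$generation), x$best_phi))
  invisible(x)
}

init_individual <- function(condition, n) {
  A <- matrix(0, n, n)
  if (condition == "fixed") {
    for (i in seq_len(n))
      A[i, sample(setdiff(seq_len(n), i), 2)] <- 0.25
  } else {
    for (i in seq_len(n)) {
      repeat {
        links <- setdiff(seq_len(n), i)[
          stats::runif(n - 1) < 2 / (n - 1)]
        if (length(links) > 0) break
      }
      A[i, links] <- 0.5 / length(links)
    }
  }
  A
}

# one GA mutation; constraint is preserved by construction, stationarity
# is re-checked and the mutation resampled on violation
mutate_individual <- function(A, condition, n) {
  for (attempt in 1:100) {
    B <- if (condition == "fixed") mutate_fixed(A, n) else mutate_vary(A, n)
    if (max(Mod(eigen(B, only.values = TRUE)$values)) < 1 - 1e-9) return(B)
  }
  stop("failed to produce a stationary mutant after 100 attempts",
       call. = FALSE)
}

mutate_fixed <- function(A, n) {
  links <- which(A != 0)
  drop <- sample(links, 2)
  for (l in drop) {
    i <- (l - 1) %% n + 1
    A[l] <- 0
    free <- setdiff(which(A[i, ] == 0), i)
    A[i, sample(free, 1)] <- 0.25
  }
  A
}

mutate_vary <- function(A, n) {
  op <- sample(c("add", "remove", "swap"), 1)
  empty <- setdiff(which(A == 0), which(diag(n) == 1))
  links <- which(A != 0)
  if (op == "add" && length(empty) >= 2) {
    A[sample(empty, 2)] <- 1  # placeholder; renormalized below
  } else if (op == "remove") {
    # keep every row non-empty
    rows <- (links - 1) %% n + 1
    removable <- links[rows %in% which(tabulate(rows, n) > 1)]
    if (length(removable) >= 2) A[sample(removable, 2)] <- 0
  } else if (op == "swap" && length(empty) >= 2 && length(links) >= 2) {
    rows <- (links - 1) %% n + 1
    movable <- links[rows %in% which(tabulate(rows, n) > 1)]
    src <- sample(if (length(movable) >= 2) movable else links, 2)
    dst <- sample(empty, 2)
    A[src] <- 0
    A[dst] <- 1
  }
  renormalize_afference(A, n)
}

renormalize_afference <- function(A, n) {
  for (i in seq_len(n)) {
    k <- sum(A[i, ] != 0)
    if (k == 0) { # re-seed an empty row
      A[i, sample(setdiff(seq_len(n), i), 1)] <- 1
      k <- 1
    }
    A[i, A[i, ] != 0] <- 0.5 / k
  }
  A
}

#' Sensitivity of Phi-E to single mutations
#'
#' Applies `n_mutations` independent single mutations of the given
#' condition to a model's coefficient matrix, recomputes Phi-E
#' analytically after each, and reports the percentage decrease
#' relative to the unmutated network.
#'
#' @param model A stationary MVAR(1) [mvar_model()] satisfying the
#'   condition's constraint.
#' @param condition `"fixed"` or `"vary"` — which mutation operator to use.
#' @param n_mutations Number of independent mutations.
#' @param seed Integer seed.
#' @return Numeric vector of percentage decreases
#'   (`(phi_before - phi_after) / phi_before * 100`), one per mutation.
#' @export
mutation_sensitivity <- function(model, condition = c("fixed", "vary"),
                                 n_mutations = 200, seed = 1) {
  condition <- match.arg(condition)
  stopifnot(inherits(model, "mvar_model"))
  if (model$p != 1) stop("mutation analysis needs an MVAR(1) model",
                         call. = FALSE)
  if (n_mutations == 0) return(numeric(0))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- model$n
  parts <- parts_for_n(n)
  A <- model$coeffs[[1]]
  phi0 <- phi_e_value_fast(A, model$noise_cov, parts)
  vapply(seq_len(n_mutations), function(i) {
    B <- mutate_individual(A, condition, n)
    (phi0 - phi_e_value_fast(B, model$noise_cov, parts)) / phi0 * 100
  }, numeric(1))
}

#' Sweep one connection strength and track Phi-E and the MIB
#'
#' Recomputes analytic Phi-E along a grid of strengths for a single
#' directed connection, flagging grid intervals where the minimum
#' information bipartition changes — the mechanism behind discontinuities
#' in Phi-E under continuous parameter change, since each bipartition's
#' effective information varies continuously but the identity of the MIB
#' can switch.
#'
#' @param model A stationary MVAR(1) [mvar_model()].
#' @param source,target Element indices of the swept connection
#'   (coefficient entry `[target, source]`).
#' @param weights Numeric grid of strengths.
#' @return A tibble of class `phi_sweep`: columns `weight`, `phi`,
#'   `mib_part1`, `mib_part2`, `mib_changed`, `stationary`. Non-stationary
#'   grid points are skipped with a warning (`phi = NA`).
#' @export
connection_sweep <- function(model, source, target, weights) {
  stopifnot(inherits(model, "mvar_model"))
  if (model$p != 1) stop("connection sweep needs an MVAR(1) model",
                         call. = FALSE)
  rows <- lapply(weights, function(w) {
    A <- model$coeffs[[1]]
    A[target, source] <- w
    m <- tryCatch(mvar_model(list(A), model$noise_cov),
                  error = function(e) NULL)
    if (is.null(m)) {
      warning("skipping non-stationary grid point weight = ", w,
              call. = FALSE)
      return(tibble::tibble(weight = w, phi = NA_real_,
                            mib_part1 = NA_character_,
                            mib_part2 = NA_character_, stationary = FALSE))
    }
    r <- phi_analytic(m, tau = 1)
    tibble::tibble(weight = w, phi = r$value,
                   mib_part1 = format_part(r$mib$part1),
                   mib_part2 = format_part(r$mib$part2), stationary = TRUE)
  })
  out <- dplyr::bind_rows(rows)
  out$mib_changed <- c(FALSE, utils::head(out$mib_part1, -1) !=
                         out$mib_part1[-1])
  out$mib_changed[is.na(out$mib_changed)] <- FALSE
  class(out) <- c("phi_sweep", class(out))
  out
}
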