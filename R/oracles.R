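#' Galton-Watson avalanche ensembles
#'
#' Simulates independent branching trees and reports them in the same tabular
#' form as [run_ensemble()]: `S` is the total progeny (root included), `T`
#' the extinction generation, and the profile the per-generation population.
#' A critical branching process (offspring mean 1) is the mean-field
#' reference for a network at branching parameter 1, with size exponent
#' `tau = 3/2`, duration exponent `alpha = 2`, and `<S>(T) ~ T^2` — these
#' analytic values serve as calibration targets for the avalanche analyzer.
#'
#' Offspring laws: `"binary"` (0 or 2 children, probability `mean / 2` of
#' doubling — note total progeny is then always odd), `"geometric"`, and
#' `"poisson"`. Each generation is advanced with a single compound draw, so
#' the cost per tree is proportional to its duration, not its size.
#'
#' @param n_avalanches number of trees.
#' @param offspring offspring law.
#' @param mean_offspring offspring mean in (0, 2]; 1 is critical.
#' @param max_generations cap per tree; trees still alive at the cap are
#'   reported with `terminated_by = "cap"` (exclude them from fits).
#' @param seed optional RNG seed.
#' @param keep_profiles keep per-generation population profiles.
#' @return An `avalanche_ensemble` tibble (no `trigger` column semantics:
#'   every tree starts from a single root).
#' @export
#' @examples
#' gw <- gw_avalanches(1000, mean_offspring = 0.5, seed = 1)
#' mean(gw$S) # ~ 1 / (1 - 0.5) = 2
gw_avalanches <- function(n_avalanches,
                          offspring = c("binary", "geometric", "poisson"),
                          mean_offspring = 1, max_generations = 1e6,
                          seed = NULL, keep_profiles = TRUE) {
  n_avalanches <- check_count(n_avalanches, "n_avalanches")
  offspring <- match.arg(offspring)
  m <- mean_offspring
  if (!is.numeric(m) || length(m) != 1L || m <= 0 ||
    (offspring == "binary" && m > 2)) {
    stop_invalid("`mean_offspring` must be in (0, 2] (binary) or > 0.")
  }
  advance <- switch(offspring,
    binary = function(z) 2 * stats::rbinom(1L, z, m / 2),
    geometric = function(z) stats::rnbinom(1L, size = z, prob = 1 / (1 + m)),
    poisson = function(z) stats::rpois(1L, m * z)
  )
  with_seed(seed, {
    S <- numeric(n_avalanches)
    T_ <- integer(n_avalanches)
    term <- character(n_avalanches)
    profiles <- if (keep_profiles) vector("list", n_avalanches) else NULL
    for (a in seq_len(n_avalanches)) {
      z <- 1
      s <- 1
      prof <- numeric(64L)
      prof[1L] <- 1
      t <- 1L
      capped <- FALSE
      repeat {
        if (t >= max_generations) {
          capped <- TRUE
          break
        }
        z <- advance(z)
        if (z == 0) break
        t <- t + 1L
        if (t > length(prof)) prof <- c(prof, numeric(length(prof)))
        prof[t] <- z
        s <- s + z
      }
      S[a] <- s
      T_[a] <- t
      term[a] <- if (capped) "cap" else "natural"
      if (keep_profiles) profiles[[a]] <- prof[seq_len(t)]
    }
    out <- tibble::tibble(
      avalanche_id = seq_len(n_avalanches),
      trigger = NA_integer_,
      S = S, T = T_, terminated_by = term
    )
    if (keep_profiles) out$profile <- profiles
    attr(out, "t_e") <- NA_real_
    class(out) <- c("avalanche_ensemble", class(out))
    out
  })
}

#' Sample from a discrete truncated power law
#'
#' Draws from `P(x) ~ x^-tau` on the integers `[x_min, x_max]` by inverse
#' lookup — a synthetic-data generator for exponent-recovery checks of
#' [fit_powerlaw_tail()].
#'
#' @param n sample size.
#' @param tau density exponent.
#' @param x_max,x_min support bounds.
#' @param seed optional RNG seed.
#' @return Integer-valued numeric samples.
#' @export
rzipf <- function(n, tau, x_max, x_min = 1, seed = NULL) {
  support <- seq(x_min, x_max)
  p <- support^(-tau)
  with_seed(seed, {
    support[sample.int(length(support), n, replace = TRUE, prob = p)]
  })
}

#' Brute-force damage-spreading branching parameter
#'
#' Literal counterfactual oracle for [branching_parameter()]: for every node,
#' flip its state, recompute the entire next deterministic state vector from
#' scratch, and count the positions that differ from the unflipped update.
#' O(N * E) per call — intended for tests on small networks (N <= 1000).
#'
#' @param net a `socnet` object.
#' @param states Boolean (0/1) state vector.
#' @return `lambda`, the mean damage count.
#' @export
brute_force_branching <- function(net, states) {
  n <- n_nodes(net)
  if (n > 1000L) stop_invalid("oracle is O(N*E); use branching_parameter() for large N.")
  states <- as.integer(states)
  base <- step_deterministic(net, states)
  damage <- vapply(seq_len(n), function(i) {
    flipped <- states
    flipped[i] <- 1L - flipped[i]
    sum(step_deterministic(net, flipped) != base)
  }, numeric(1))
  mean(damage)
}

#' Deterministic toy networks with known avalanche traces
#'
#' Small named fixtures used throughout the tests, each with an exactly known
#' deterministic avalanche outcome (threshold 0, fatigue disabled):
#' \describe{
#'   \item{isolated}{5 nodes, no links: any trigger gives S = 1, T = 1.}
#'   \item{chain3}{1 -> 2 -> 3 with +1 weights: trigger 1 gives S = 3, T = 3,
#'     profile (1, 1, 1).}
#'   \item{cycle2}{1 <-> 2 with +1 weights: a period-2 limit cycle without
#'     fatigue; any finite `t_e` terminates it with probability 1.}
#'   \item{tree_d3}{perfect binary out-tree of depth 3 (15 nodes): trigger at
#'     the root gives S = 15, T = 4, profile (1, 2, 4, 8).}
#'   \item{complete3}{complete +1 digraph on 3 nodes: from the all-off state,
#'     flipping any node changes both others, so lambda = 2.}
#'   \item{cancel4}{mixed-sign cancellation motif 1 -> {2, 4} (+1),
#'     2 -> 3 (+1), 4 -> 3 (-1): node 3's inputs cancel, so trigger 1 gives
#'     S = 3, T = 2.}
#' }
#'
#' @return A named list of `socnet` objects.
#' @export
toy_networks <- function() {
  edge <- function(s, t, w = 1L) tibble::tibble(source = s, target = t, weight = w)
  tree_edges <- do.call(rbind, lapply(1:7, function(i) {
    edge(c(i, i), c(2L * i, 2L * i + 1L))
  }))
  list(
    isolated = signed_network(5, name = "isolated"),
    chain3 = signed_network(3, edge(c(1L, 2L), c(2L, 3L)), name = "chain3"),
    cycle2 = signed_network(2, edge(c(1L, 2L), c(2L, 1L)), name = "cycle2"),
    tree_d3 = signed_network(15, tree_edges, name = "tree_d3"),
    complete3 = signed_network(
      3,
      edge(c(1L, 1L, 2L, 2L, 3L, 3L), c(2L, 3L, 1L, 3L, 1L, 2L)),
      name = "complete3"
    ),
    cancel4 = signed_network(
      4,
      rbind(
        edge(1L, 2L), edge(1L, 4L), edge(2L, 3L),
        edge(4L, 3L, w = -1L)
      ),
      name = "cancel4"
    )
  )
}
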