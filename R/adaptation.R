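#' Lagged Pearson correlation between a node and one of its inputs
#'
#' Correlation between the target series shifted one step ahead,
#' `n_i(t + 1)`, and the source series `n_j(t)`, over a recorded trajectory
#' window — the lag accounts for the one-step signal transmission time. If
#' either series is constant over the window (a frozen node has standard
#' deviation 0 and the Pearson coefficient is undefined) the correlation is
#' taken to be 0, the neutral value for the rewiring acceptance comparison.
#'
#' @param traj integer trajectory matrix (nodes x time), width >= 2.
#' @param target target node id `i`.
#' @param source source node id `j`.
#' @return A correlation in \[-1, 1\].
#' @export
lagged_pearson <- function(traj, target, source) {
  tw <- ncol(traj)
  if (tw < 2L) stop_invalid("trajectory must span at least 2 steps.")
  x <- traj[target, 2L:tw]
  y <- traj[source, 1L:(tw - 1L)]
  # a frozen series (or a single-step window) has no variance: convention 0
  if (length(x) < 2L || sd(x) == 0 || sd(y) == 0) {
    return(0)
  }
  cor(x, y)
}

#' Average input correlation of a node
#'
#' Mean lagged Pearson correlation over the existing in-links of node `i`;
#' correlations are only measured where links are present. A node without
#' in-links has average input correlation 0 by convention.
#'
#' @param net a `socnet` object.
#' @param traj trajectory matrix (nodes x time).
#' @param node node id `i`.
#' @return The mean input correlation `<C>_i`.
#' @export
avg_input_correlation <- function(net, traj, node) {
  sources <- which(net$W[node, ] != 0L)
  if (length(sources) == 0L) {
    return(0)
  }
  mean(vapply(sources, function(j) lagged_pearson(traj, node, j), numeric(1)))
}

#' Damage-spreading branching parameter
#'
#' For each node `i`, counts the descendant (out-neighbour) nodes whose next
#' deterministic state would differ if the present state of `i` were flipped —
#' both the present states and the sign of the connecting links enter through
#' the threshold rule. The branching parameter `lambda` is this damage count
#' averaged over all `N` nodes: `lambda < 1` marks a subcritical and
#' `lambda > 1` a supercritical configuration, with `lambda = 1` the critical
#' point the rewiring rule self-organises towards.
#'
#' @param net a `socnet` object.
#' @param states Boolean (0/1) state vector the counterfactual is evaluated on.
#' @return `lambda >= 0`.
#' @export
branching_parameter <- function(net, states) {
  states <- as.integer(states)
  idx <- which(net$W != 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(0)
  }
  tgt <- idx[, 1L]
  src <- idx[, 2L]
  w <- net$W[idx]
  f <- as.integer(net$W %*% states)
  margin <- f[tgt] - net$theta[tgt]
  base <- margin > 0L
  flipped <- margin + (1L - 2L * states[src]) * w > 0L
  sum(base != flipped) / n_nodes(net)
}

#' Adaptation run configuration
#'
#' Bundles and validates the parameters of the correlation-based rewiring
#' loop. The correlation window `t_corr` and the transient `t_trans` set the
#' time-scale separation between the fast node dynamics and the slow rewiring
#' (at least two orders of magnitude at the defaults of 100 steps each).
#'
#' @param n_epochs number of rewiring epochs.
#' @param t_corr window length (steps) for each correlation measurement, >= 2.
#' @param t_trans transient steps after each rewiring decision.
#' @param beta inverse temperature of the stochastic dynamics. The default 5
#'   suits threshold-0 nodes; threshold-1 runs need a lower value (e.g. 2.5)
#'   so that thermal noise can still trigger avalanches.
#' @param eps input shift in (0, 1).
#' @param p_activating sign probability for inserted links.
#' @param fixed_ratio optional activating-link ratio in (0, 1] to pin after
#'   every epoch (`NULL` for the free-running rule).
#' @param snapshot_band export a network snapshot whenever
#'   `|lambda - 1| <= snapshot_band`.
#' @param lambda_smooth window (epochs) for the running-mean `lambda` column
#'   reported in the trace; plot-level smoothing only, not part of the
#'   algorithm.
#' @param snapshot_after only retain snapshots from epochs after this one —
#'   near-critical crossings early in a run are transients, not evolved
#'   critical configurations.
#' @param max_snapshots cap on retained snapshots (each stores the full
#'   network).
#' @param seed optional RNG seed for the whole run.
#' @return An `adaptation_config` object (a validated list).
#' @export
adaptation_config <- function(n_epochs = 400L, t_corr = 100L, t_trans = 100L,
                              beta = 5, eps = 0.5, p_activating = 0.5,
                              fixed_ratio = NULL, snapshot_band = 0.05,
                              lambda_smooth = 10L, snapshot_after = 0L,
                              max_snapshots = 20L, seed = NULL) {
  cfg <- list(
    n_epochs = check_count(n_epochs, "n_epochs"),
    t_corr = check_count(t_corr, "t_corr", min = 2L),
    t_trans = check_count(t_trans, "t_trans"),
    beta = beta, eps = eps,
    p_activating = check_prob(p_activating, "p_activating"),
    fixed_ratio = fixed_ratio,
    snapshot_band = snapshot_band,
    lambda_smooth = check_count(lambda_smooth, "lambda_smooth"),
    snapshot_after = check_count(snapshot_after, "snapshot_after", min = 0L),
    max_snapshots = max_snapshots,
    seed = seed
  )
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0) {
    stop_invalid("`beta` must be a single finite number > 0.")
  }
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0 || eps >= 1) {
    stop_invalid("`eps` must be in (0, 1).")
  }
  if (!is.null(fixed_ratio) &&
    (!is.numeric(fixed_ratio) || fixed_ratio <= 0 || fixed_ratio > 1)) {
    stop_invalid("`fixed_ratio` must be in (0, 1] or NULL.")
  }
  if (!is.numeric(snapshot_band) || snapshot_band < 0) {
    stop_invalid("`snapshot_band` must be >= 0.")
  }
  structure(cfg, class = "adaptation_config")
}

# rate guideline: thermal activation of idle nodes should be rare, so that
# avalanches are noise-triggered but not noise-dominated
check_noise_rate <- function(net, cfg) {
  p_idle <- activation_probability(0, min(net$theta), cfg$beta, cfg$eps)
  if (p_idle > 0.05) {
    warn(
      sprintf(
        paste0(
          "idle-node activation probability is %.3f (> 0.05); ",
          "choose beta/eps so that thermal activation occurs at a low rate."
        ),
        p_idle
      ),
      class = "socnet_noise_warning"
    )
  }
  invisible(p_idle)
}

#' Correlation-based rewiring: the self-organization loop
#'
#' Runs the adaptive rewiring algorithm. Each epoch: (1) pick one node `i`
#' uniformly at random; (2) run `t_corr` stochastic steps and measure the
#' average input correlation `<C>_i`; (3) with probability 1/2 insert an
#' in-link of random sign at `i` from a previously unlinked non-self source,
#' otherwise remove one of `i`'s in-links (an infeasible action falls back to
#' the other, flagged in the trace); (4) run `t_corr` further steps and
#' remeasure `<C>_i`; (5) keep the change if and only if `<C>_i` strictly
#' increased, otherwise revert it bit-exactly; (6) run `t_trans` transient
#' steps. With `fixed_ratio` set, link signs are rebalanced to the pinned
#' activating ratio after every epoch. The branching parameter is measured on
#' the instantaneous state at each epoch end, and a snapshot of the network is
#' retained whenever it falls within `snapshot_band` of the critical value 1.
#'
#' @param net the initial `socnet` (e.g. from [make_random_network()]).
#' @param cfg an [adaptation_config()].
#' @param init_states optional initial Boolean state vector (default all-off).
#' @return A `socnet_evolution` object: list with `network` (final `socnet`),
#'   `trace` (one tibble row per epoch: `epoch`, `K`, `lambda`,
#'   `lambda_smooth`, `r_plus`, `action`, `fallback`, `accepted`, `node`,
#'   `c_before`, `c_after`), `snapshots` (list of near-critical `socnet`
#'   snapshots), `final_state`, and `config`.
#' @export
#' @examples
#' net <- make_random_network(32, k_init = 0)
#' ev <- evolve(net, adaptation_config(n_epochs = 10, t_corr = 20, t_trans = 20, seed = 1))
#' ev$trace
evolve <- function(net, cfg, init_states = NULL) {
  stopifnot(inherits(net, "socnet"), inherits(cfg, "adaptation_config"))
  n <- n_nodes(net)
  check_noise_rate(net, cfg)
  if (is.null(init_states)) init_states <- rep.int(0L, n)
  with_seed(cfg$seed, {
    state <- dynamics_state(init_states, beta = cfg$beta, eps = cfg$eps)
    ne <- cfg$n_epochs
    epoch_v <- seq_len(ne)
    K_v <- lambda_v <- rp_v <- cb_v <- ca_v <- numeric(ne)
    action_v <- character(ne)
    fallback_v <- accepted_v <- logical(ne)
    node_v <- integer(ne)
    snapshots <- list()

    for (epoch in epoch_v) {
      i <- sample.int(n, 1L)
      win <- run_window(net, state, cfg$t_corr)
      state <- win$state
      c_before <- avg_input_correlation(net, win$trajectory, i)

      want_insert <- runif(1L) < 0.5
      fallback <- FALSE
      res <- NULL
      if (want_insert) {
        res <- tryCatch(add_in_link(net, i, cfg$p_activating),
          socnet_no_candidate = function(e) NULL
        )
        if (is.null(res)) {
          fallback <- TRUE
          res <- remove_in_link(net, i)
        }
      } else {
        res <- tryCatch(remove_in_link(net, i),
          socnet_no_link = function(e) NULL
        )
        if (is.null(res)) {
          fallback <- TRUE
          res <- add_in_link(net, i, cfg$p_activating)
        }
      }
      candidate <- res$network

      win <- run_window(candidate, state, cfg$t_corr)
      state <- win$state
      c_after <- avg_input_correlation(candidate, win$trajectory, i)

      accepted <- c_after > c_before
      net <- if (accepted) candidate else revert_link(candidate, res$link)

      if (!is.null(cfg$fixed_ratio) && n_links(net) > 0L) {
        net <- rebalance_link_signs(net, cfg$fixed_ratio)
      }

      win <- run_window(net, state, cfg$t_trans)
      state <- win$state
      lambda <- branching_parameter(net, state$states)

      K_v[epoch] <- avg_connectivity(net)
      lambda_v[epoch] <- lambda
      rp_v[epoch] <- activating_ratio(net)
      cb_v[epoch] <- c_before
      ca_v[epoch] <- c_after
      action_v[epoch] <- res$link$action
      fallback_v[epoch] <- fallback
      accepted_v[epoch] <- accepted
      node_v[epoch] <- i

      if (abs(lambda - 1) <= cfg$snapshot_band && epoch > cfg$snapshot_after &&
        length(snapshots) < cfg$max_snapshots) {
        snap <- net
        snap$meta$epoch <- epoch
        snap$meta$lambda <- lambda
        snapshots[[length(snapshots) + 1L]] <- snap
      }
    }

    trace <- tibble::tibble(
      epoch = epoch_v, K = K_v, lambda = lambda_v,
      lambda_smooth = running_mean(lambda_v, cfg$lambda_smooth),
      r_plus = rp_v, action = action_v, fallback = fallback_v,
      accepted = accepted_v, node = node_v, c_before = cb_v, c_after = ca_v
    )
    structure(
      list(
        network = net, trace = trace, snapshots = snapshots,
        final_state = state, config = cfg
      ),
      class = "socnet_evolution"
    )
  })
}

# trailing running mean over the last `width` values (shorter at the start)
running_mean <- function(x, width) {
  cs <- cumsum(x)
  n <- length(x)
  lo <- pmax(seq_len(n) - width, 0L)
  (cs - c(0, cs)[lo + 1L]) / (seq_len(n) - lo)
}

#' @export
print.socnet_evolution <- function(x, ...) {
  tr <- x$trace
  last <- tail(tr, max(1L, nrow(tr) %/% 4L))
  cat(sprintf(
    "<socnet_evolution> %d epochs; final <K> = %.3f, final-quarter mean lambda = %.3f, %d snapshots\n",
    nrow(tr), tail(tr$K, 1L), mean(last$lambda), length(x$snapshots)
  ))
  invisible(x)
}

#' Stimulant perturbation experiment
#'
#' Evolves a network of threshold-`theta_before` nodes, then at `switch_epoch`
#' resets every node's activation threshold to `theta_after` at once —
#' mimicking a stimulant substance that raises neuronal excitability — and
#' continues the adaptation. With `theta_before = 1` and `theta_after = 0`
#' the switch throws the evolved network into the supercritical regime
#' (`lambda > 1`) and the rewiring rule responds by pruning links until the
#' branching parameter returns towards 1.
#'
#' @param net the initial `socnet`; its thresholds are overwritten with
#'   `theta_before`.
#' @param cfg an [adaptation_config()]; `cfg$n_epochs` is the total epoch
#'   count across both phases.
#' @param switch_epoch epoch after which the thresholds are reset.
#' @param theta_before,theta_after thresholds before and after the switch.
#' @return A `socnet_stimulant` object: list with `trace` (combined, with a
#'   `phase` column), `pre`, `post` (the two `socnet_evolution` runs) and
#'   `switch_epoch`.
#' @export
stimulant_experiment <- function(net, cfg, switch_epoch,
                                 theta_before = 1L, theta_after = 0L) {
  stopifnot(inherits(net, "socnet"), inherits(cfg, "adaptation_config"))
  switch_epoch <- check_count(switch_epoch, "switch_epoch")
  if (switch_epoch >= cfg$n_epochs) {
    stop_invalid("`switch_epoch` must be smaller than cfg$n_epochs.")
  }
  thresholds(net) <- theta_before
  with_seed(cfg$seed, {
    cfg_pre <- cfg
    cfg_pre$n_epochs <- switch_epoch
    cfg_pre$seed <- NULL
    pre <- evolve(net, cfg_pre)

    net_post <- pre$network
    thresholds(net_post) <- theta_after
    cfg_post <- cfg
    cfg_post$n_epochs <- cfg$n_epochs - switch_epoch
    cfg_post$seed <- NULL
    post <- evolve(net_post, cfg_post, init_states = pre$final_state$states)

    trace <- dplyr::bind_rows(
      dplyr::mutate(pre$trace, phase = "pre"),
      dplyr::mutate(post$trace,
        epoch = .data$epoch + switch_epoch, phase = "post"
      )
    )
    structure(
      list(trace = trace, pre = pre, post = post, switch_epoch = switch_epoch),
      class = "socnet_stimulant"
    )
  })
}
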