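# Independent reference implementations used as oracles. These deliberately
# avoid the package's own update code paths.

# Graph-theoretic avalanche oracle for purely activating (+1) networks with
# threshold 0 and fatigue disabled: activity spreads along directed edges one
# step per hop, so the set active at time t is exactly the set of nodes at
# shortest-path distance t - 1 from the trigger.
bfs_avalanche <- function(net, trigger) {
  g <- as_igraph(net)
  d <- igraph::distances(g, v = trigger, mode = "out")[1L, ]
  d <- d[is.finite(d)]
  profile <- as.integer(table(factor(d, levels = 0:max(d))))
  list(S = length(d), T = max(d) + 1L, profile = profile)
}

# Literal per-node R simulator of the deterministic threshold update,
# written with explicit loops (no matrix products).
ref_step_det <- function(net, states, theta = net$theta) {
  n <- length(states)
  out <- integer(n)
  for (i in seq_len(n)) {
    f <- 0L
    for (j in seq_len(n)) {
      if (states[j] == 1L) f <- f + net$W[i, j]
    }
    out[i] <- as.integer(f - theta[i] > 0L)
  }
  out
}

# Fatigue-free avalanche via the reference step (works for any signs/cycles
# as long as it terminates; callers cap the step count).
ref_avalanche <- function(net, trigger, max_steps = 1000L) {
  n <- n_nodes(net)
  s <- integer(n)
  s[trigger] <- 1L
  ever <- s
  profile <- integer(0)
  t <- 0L
  while (sum(s) > 0L && t < max_steps) {
    t <- t + 1L
    profile[t] <- sum(s)
    s <- ref_step_det(net, s)
    ever <- pmax(ever, s)
  }
  list(S = sum(ever), T = t, profile = profile)
}

# Random directed acyclic network with +1/-1 weights: edges only from lower
# to higher node ids, so termination without fatigue is guaranteed.
random_dag <- function(n, p_edge = 0.2, p_activating = 0.8, theta = 0L) {
  edges <- NULL
  for (j in seq_len(n - 1L)) {
    for (i in seq(j + 1L, n)) {
      if (runif(1) < p_edge) {
        w <- if (runif(1) < p_activating) 1L else -1L
        edges <- rbind(edges, data.frame(source = j, target = i, weight = w))
      }
    }
  }
  signed_network(n, edges, theta = theta)
}
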