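#' Node input fields
#'
#' The input field of node `i` is the signed sum of its active inputs,
#' `f_i = sum_j w_ij n_j`, an integer; absent links contribute 0.
#'
#' @param net a `socnet` object.
#' @param states Boolean (0/1) state vector of length `N`.
#' @param node optional node id; when `NULL` all fields are returned.
#' @return An integer vector (or scalar when `node` is given).
#' @export
input_field <- function(net, states, node = NULL) {
  states <- as.integer(states)
  if (length(states) != n_nodes(net)) {
    stop_invalid("`states` must have one entry per node.")
  }
  f <- as.integer(net$W %*% states)
  if (is.null(node)) f else f[node]
}

#' Glauber activation probability
#'
#' Probability that a node becomes active given its input field:
#' `g_beta(x) = 1 / (1 + exp(-2 beta x))` with `x = f - theta - eps`. The
#' input shift `eps` in (0, 1) makes spontaneous activation of an idle node
#' rare but nonzero — the noise that triggers avalanches — and recovers the
#' strict `f - theta > 0` deterministic rule in the limit `beta -> Inf`.
#'
#' @param field integer input field(s) `f`.
#' @param theta activation threshold(s).
#' @param beta inverse temperature, `beta > 0` (may be `Inf`).
#' @param eps input shift in (0, 1).
#' @return Activation probabilities.
#' @export
activation_probability <- function(field, theta = 0, beta = 5, eps = 0.5) {
  x <- field - theta - eps
  if (is.infinite(beta)) {
    return(as.numeric(x > 0))
  }
  1 / (1 + exp(-2 * beta * x))
}

#' Dynamics state container
#'
#' Bundles a Boolean state vector with the simulation time and the update
#' parameters (inverse temperature `beta` and input shift `eps`).
#'
#' @param states Boolean (0/1) vector.
#' @param time integer time step.
#' @param beta inverse temperature (finite for stochastic updates).
#' @param eps input shift in (0, 1).
#' @return A `dynamics_state` object.
#' @export
dynamics_state <- function(states, time = 0L, beta = 5, eps = 0.5) {
  states <- as.integer(states)
  if (any(!states %in% c(0L, 1L))) stop_invalid("states must be 0/1.")
  if (!is.numeric(beta) || beta <= 0) stop_invalid("`beta` must be > 0.")
  if (!is.numeric(eps) || eps <= 0 || eps >= 1) stop_invalid("`eps` must be in (0, 1).")
  structure(
    list(states = states, time = as.integer(time), beta = beta, eps = eps),
    class = "dynamics_state"
  )
}

#' One synchronous stochastic update
#'
#' All nodes are updated in parallel: node `i` becomes active with probability
#' [activation_probability()] of its current input field. Exactly `N` uniform
#' draws are consumed, in node-index order, so seeded runs are reproducible.
#'
#' @param net a `socnet` object.
#' @param state a `dynamics_state` with finite `beta`.
#' @return The updated `dynamics_state` (time advanced by 1).
#' @export
step_stochastic <- function(net, state) {
  if (is.infinite(state$beta)) {
    stop_invalid("`beta` must be finite for the stochastic update; use step_deterministic().")
  }
  f <- input_field(net, state$states)
  p <- activation_probability(f, net$theta, state$beta, state$eps)
  state$states <- as.integer(runif(length(p)) < p)
  state$time <- state$time + 1L
  state
}

#' One synchronous deterministic update
#'
#' The zero-temperature limit of the stochastic rule: node `i` becomes active
#' if and only if `f_i - theta_i > 0` (strictly positive net activating
#' input). A pure function of the state vector — no RNG is consumed.
#'
#' @param net a `socnet` object.
#' @param states Boolean (0/1) state vector.
#' @param theta effective thresholds; defaults to the network's thresholds.
#' @return The next Boolean state vector.
#' @export
step_deterministic <- function(net, states, theta = NULL) {
  if (is.null(theta)) theta <- net$theta
  f <- input_field(net, states)
  as.integer(f - theta > 0L)
}

#' Run a window of stochastic updates
#'
#' Applies [step_stochastic()] `n_steps` times, recording every intermediate
#' state. The recorded window is the trajectory over which input correlations
#' are measured during adaptation.
#'
#' @param net a `socnet` object.
#' @param state a `dynamics_state` with finite `beta`.
#' @param n_steps number of steps (>= 1).
#' @return A list with `state` (the final `dynamics_state`) and `trajectory`
#'   (an `N x n_steps` integer matrix; column `t` is the state after step `t`).
#' @export
run_window <- function(net, state, n_steps) {
  n_steps <- check_count(n_steps, "n_steps")
  if (is.infinite(state$beta)) {
    stop_invalid("`beta` must be finite for stochastic windows.")
  }
  traj <- cpp_run_window(
    net$W, net$theta, state$beta, state$eps,
    state$states, n_steps
  )
  state$states <- traj[, n_steps]
  state$time <- state$time + n_steps
  list(state = state, trajectory = traj)
}
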