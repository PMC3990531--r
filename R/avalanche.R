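term_labels <- c("natural", "exhaust", "cap")

check_t_e <- function(t_e) {
  if (length(t_e) != 1L || is.na(t_e) ||
    (!is.infinite(t_e) && (t_e < 1 || t_e != trunc(t_e)))) {
    stop_invalid("`t_e` must be a positive integer or Inf (fatigue disabled).")
  }
  if (is.infinite(t_e)) 0L else as.integer(t_e)
}

#' Run one deterministic avalanche
#'
#' Starts from the fully quiescent network, activates the trigger node at
#' `t = 1`, and iterates synchronous deterministic threshold updates
#' (`n_i = 1` iff `f_i - theta_i^eff > 0`) until all nodes are off. The
#' exhaust mechanism models neurotransmitter depletion: after each update,
#' every node raises its effective threshold by 1 with probability equal to
#' its own average activity over the last `t_e` steps (active steps divided
#' by `t_e`). This fatigue is what lets the dynamics step out of periodic
#' attractors, so every avalanche terminates. In the default `"transient"`
#' mode the elevation is redrawn each step, so nodes recover as their
#' activity leaves the exhaust window — long avalanches can travel through
#' fresh territory far beyond `t_e` steps, preserving the duration scaling.
#' In `"sticky"` mode a raised threshold stays raised until the avalanche
#' ends, which caps durations at a small multiple of `t_e`. `t_e = Inf`
#' disables fatigue (useful on acyclic networks).
#'
#' @param net a `socnet` object.
#' @param trigger node id (1-based) activated at `t = 1`.
#' @param t_e exhaust window length in steps (positive integer or `Inf`).
#' @param fatigue `"transient"` (per-step elevation draws, the default) or
#'   `"sticky"` (elevations persist for the rest of the avalanche).
#' @param max_steps safety cap on avalanche length.
#' @param seed optional RNG seed (fatigue draws are the only randomness).
#' @param init_states if supplied, must be all-off; avalanches are defined on
#'   a quiescent network.
#' @return An `avalanche` object: list with `events` (tibble of active
#'   `(t, node)` events), `S` (distinct nodes activated), `T` (steps from
#'   first activation to termination), `profile` (active-node count per step,
#'   length `T`), `terminated_by` (`"natural"`, `"exhaust"`, or `"cap"`),
#'   `trigger`, and `t_e`.
#' @export
#' @examples
#' chain <- toy_networks()$chain3
#' run_avalanche(chain, trigger = 1) # S = 3, T = 3
run_avalanche <- function(net, trigger, t_e = 20,
                          fatigue = c("transient", "sticky"), max_steps = 1e6,
                          seed = NULL, init_states = NULL) {
  fatigue <- match.arg(fatigue)
  stopifnot(inherits(net, "socnet"))
  trigger <- check_count(trigger, "trigger")
  if (trigger > n_nodes(net)) stop_invalid("`trigger` out of range.")
  if (!is.null(init_states) && any(as.integer(init_states) != 0L)) {
    abort("avalanches must start from a quiescent (all-off) network.",
      class = "socnet_contract_violation"
    )
  }
  te <- check_t_e(t_e)
  res <- with_seed(seed, cpp_run_avalanche(
    net$W, net$theta, trigger - 1L,
    te, as.integer(max_steps), fatigue == "sticky", TRUE
  ))
  structure(
    list(
      events = tibble::tibble(t = res$event_t, node = res$event_node + 1L),
      S = res$S, T = res$T, profile = res$profile,
      terminated_by = term_labels[res$term + 1L],
      trigger = trigger, t_e = t_e
    ),
    class = "avalanche"
  )
}

#' @export
print.avalanche <- function(x, ...) {
  cat(sprintf(
    "<avalanche> S = %d, T = %d, terminated by %s (trigger node %d)\n",
    x$S, x$T, x$terminated_by, x$trigger
  ))
  invisible(x)
}

#' Run a sequential avalanche ensemble
#'
#' Generates `n_avalanches` avalanches one after another, each triggered at a
#' uniformly random node of the quiescent network, with the exhaust state
#' reset between avalanches. This is the sampling scheme behind the
#' avalanche size/duration distributions and the `<S>(T)` scaling curve.
#'
#' @param net a `socnet` object.
#' @param n_avalanches ensemble size (>= 1).
#' @param t_e exhaust window length in steps (positive integer or `Inf`).
#' @param fatigue fatigue mode, as in [run_avalanche()].
#' @param max_steps safety cap per avalanche.
#' @param seed optional RNG seed; fixed seeds give bit-identical ensembles.
#' @param keep_profiles keep the per-step activity profile of every avalanche
#'   (a list column; needed for [mean_profile()] and [shape_collapse()]).
#' @return An `avalanche_ensemble`: a tibble with one row per avalanche and
#'   columns `avalanche_id`, `trigger`, `S`, `T`, `terminated_by`, and
#'   (optionally) `profile`. The node count is stored in
#'   `attr(, "n_nodes")`, the exhaust window in `attr(, "t_e")`.
#' @export
run_ensemble <- function(net, n_avalanches, t_e = 20,
                         fatigue = c("transient", "sticky"), max_steps = 1e6,
                         seed = NULL, keep_profiles = TRUE) {
  stopifnot(inherits(net, "socnet"))
  fatigue <- match.arg(fatigue)
  n_avalanches <- check_count(n_avalanches, "n_avalanches")
  te <- check_t_e(t_e)
  res <- with_seed(seed, cpp_run_ensemble(
    net$W, net$theta, n_avalanches, te,
    as.integer(max_steps), fatigue == "sticky", keep_profiles
  ))
  out <- tibble::tibble(
    avalanche_id = seq_len(n_avalanches),
    trigger = res$trigger,
    S = res$S, T = res$T,
    terminated_by = term_labels[res$term + 1L]
  )
  if (keep_profiles) out$profile <- res$profiles
  attr(out, "n_nodes") <- n_nodes(net)
  attr(out, "t_e") <- t_e
  class(out) <- c("avalanche_ensemble", class(out))
  out
}

#' Mean temporal avalanche profile at a given duration
#'
#' Averages the per-step activity profiles of all avalanches of duration `T`,
#' optionally rescaling time to the unit interval on `n_bins` points and the
#' amplitude by `1 / T^(gamma - 1)` — the scaling under which profiles of
#' different durations collapse onto a universal shape at criticality.
#'
#' @param ensemble an `avalanche_ensemble` with profiles.
#' @param duration avalanche duration `T` to average over.
#' @param n_bins number of points of the rescaled-time grid (`NULL` keeps the
#'   native `T` steps).
#' @param gamma collapse exponent used for the amplitude rescaling
#'   (`gamma = 1` leaves amplitudes untouched).
#' @return A tibble with columns `duration`, `n_avalanches`, `phase`
#'   (mid-step times rescaled to (0, 1)), and `value` (mean, rescaled active
#'   count).
#' @export
mean_profile <- function(ensemble, duration, n_bins = NULL, gamma = 1) {
  if (!"profile" %in% names(ensemble)) {
    stop_invalid("ensemble was generated with keep_profiles = FALSE.")
  }
  sel <- ensemble$T == duration
  if (!any(sel)) {
    abort(sprintf("no avalanche of duration %d in the ensemble.", duration),
      class = "socnet_empty_result"
    )
  }
  profs <- ensemble$profile[sel]
  m <- Reduce(`+`, profs) / length(profs)
  phase_native <- (seq_len(duration) - 0.5) / duration
  value <- m / duration^(gamma - 1)
  if (!is.null(n_bins)) {
    grid <- (seq_len(n_bins) - 0.5) / n_bins
    value <- if (length(phase_native) == 1L) {
      rep.int(value, n_bins)
    } else {
      approx(phase_native, value, xout = grid, rule = 2)$y
    }
    phase_native <- grid
  }
  tibble::tibble(
    duration = duration, n_avalanches = length(profs),
    phase = phase_native, value = value
  )
}
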