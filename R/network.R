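#' Signed directed Boolean threshold networks
#'
#' A `socnet` object represents a directed network of `N` Boolean nodes with
#' integer-signed coupling weights `w_ij` (+1 activating, -1 inhibiting) and a
#' per-node integer activation threshold `theta_i >= 0`. A node pair without a
#' stored link has coupling 0. Self-loops and duplicate links are disallowed.
#'
#' Internally the couplings are held as a dense integer matrix `W` with
#' `W[i, j] = w_ij`, the weight of the link `j -> i`; the tabular edge view is
#' available through [network_edges()].
#'
#' @param n_nodes number of nodes `N`.
#' @param edges optional data frame with columns `source`, `target`, `weight`
#'   (1-based node ids, weights in `{-1, +1}`).
#' @param theta integer activation threshold(s), recycled to length `N`.
#' @param name optional free-text label stored in the metadata.
#'
#' @return A `socnet` object.
#' @seealso [make_random_network()], [network_edges()], [add_in_link()]
#' @export
signed_network <- function(n_nodes, edges = NULL, theta = 0L, name = NULL) {
  n <- check_count(n_nodes, "n_nodes", min = 1L)
  theta <- as.integer(rep_len(theta, n))
  if (any(is.na(theta)) || any(theta < 0)) {
    stop_invalid("`theta` must be non-negative integers.")
  }
  W <- matrix(0L, n, n)
  if (!is.null(edges) && nrow(edges) > 0) {
    src <- as.integer(edges$source)
    tgt <- as.integer(edges$target)
    w <- as.integer(edges$weight)
    if (any(src < 1L | src > n | tgt < 1L | tgt > n)) {
      stop_invalid("edge endpoints must be node ids in 1..n_nodes.")
    }
    if (any(src == tgt)) stop_invalid("self-loops are not allowed.")
    if (any(!w %in% c(-1L, 1L))) {
      stop_invalid("weights must be +1 or -1 (unit signed couplings).")
    }
    idx <- cbind(tgt, src)
    if (anyDuplicated(idx)) stop_invalid("duplicate links are not allowed.")
    W[idx] <- w
  }
  new_socnet(W, theta, meta = list(name = name))
}

new_socnet <- function(W, theta, meta = list()) {
  structure(
    list(W = W, theta = as.integer(theta), meta = meta),
    class = "socnet"
  )
}

#' Initialise a random signed network
#'
#' Draws a network at mean in-degree `k_init`: every node receives in-links
#' from distinct random non-self sources, the total link count is
#' `round(N * k_init)`, and each weight is +1 with probability `p_activating`
#' and -1 otherwise. When `N * k_init` is not a multiple of `N`, the surplus
#' links are assigned to a random subset of nodes, one extra in-link each.
#'
#' @inheritParams signed_network
#' @param k_init target mean in-degree, `0 <= k_init <= N - 1`.
#' @param p_activating probability that a drawn link is activating (+1).
#' @param seed optional RNG seed for a reproducible draw.
#' @return A `socnet` object.
#' @export
#' @examples
#' net <- make_random_network(100, k_init = 2, p_activating = 0.5, seed = 1)
#' avg_connectivity(net)
make_random_network <- function(n_nodes, k_init, p_activating = 0.5,
                                theta = 0L, seed = NULL) {
  n <- check_count(n_nodes, "n_nodes", min = 1L)
  if (!is.numeric(k_init) || length(k_init) != 1L || is.na(k_init) || k_init < 0) {
    stop_invalid("`k_init` must be a single number >= 0.")
  }
  if (k_init > n - 1) {
    stop_invalid("`k_init` must not exceed n_nodes - 1 (no self-loops or duplicates).")
  }
  p <- check_prob(p_activating, "p_activating")
  with_seed(seed, {
    total <- round(n * k_init)
    base <- total %/% n
    extra <- total - n * base
    deg <- rep.int(base, n)
    if (extra > 0) {
      deg[sample.int(n, extra)] <- base + 1L
    }
    W <- matrix(0L, n, n)
    for (i in seq_len(n)) {
      if (deg[i] == 0L) next
      candidates <- seq_len(n)[-i]
      src <- if (length(candidates) == 1L) candidates else sample(candidates, deg[i])
      sign <- ifelse(runif(deg[i]) < p, 1L, -1L)
      W[i, src] <- sign
    }
    net <- new_socnet(W, rep_len(as.integer(theta), n),
      meta = list(name = NULL, seed = seed)
    )
    net
  })
}

#' @export
print.socnet <- function(x, ...) {
  l <- n_links(x)
  cat(sprintf(
    "<socnet> %d nodes, %d links, <K> = %.3f, r+ = %s, theta in [%d, %d]\n",
    n_nodes(x), l, avg_connectivity(x),
    if (l > 0) sprintf("%.3f", activating_ratio(x)) else "NA",
    min(x$theta), max(x$theta)
  ))
  invisible(x)
}

#' Network summary measures
#'
#' `n_nodes()` and `n_links()` count nodes and stored links; the average
#' connectivity is `<K> = n_links / N` and the activating-link ratio `r+` is
#' the fraction of positive couplings among all existing links (`NA` when the
#' network has no links).
#'
#' @param net a `socnet` object.
#' @return A single number.
#' @export
n_nodes <- function(net) nrow(net$W)

#' @rdname n_nodes
#' @export
n_links <- function(net) sum(net$W != 0L)

#' @rdname n_nodes
#' @export
avg_connectivity <- function(net) n_links(net) / n_nodes(net)

#' @rdname n_nodes
#' @export
activating_ratio <- function(net) {
  l <- n_links(net)
  if (l == 0L) {
    return(NA_real_)
  }
  sum(net$W > 0L) / l
}

#' Per-node activation thresholds
#'
#' @param net a `socnet` object.
#' @param value integer threshold(s), recycled to the number of nodes.
#' @return `thresholds()` returns the integer threshold vector.
#' @export
thresholds <- function(net) net$theta

#' @rdname thresholds
#' @export
`thresholds<-` <- function(net, value) {
  value <- as.integer(rep_len(value, n_nodes(net)))
  if (any(is.na(value)) || any(value < 0)) {
    stop_invalid("thresholds must be non-negative integers.")
  }
  net$theta <- value
  net
}

#' Edge view of a network
#'
#' @param net a `socnet` object.
#' @return A tibble with columns `source`, `target`, `weight` (1-based ids),
#'   ordered by target then source.
#' @export
network_edges <- function(net) {
  idx <- which(net$W != 0L, arr.ind = TRUE)
  out <- tibble::tibble(
    source = as.integer(idx[, 2L]),
    target = as.integer(idx[, 1L]),
    weight = as.integer(net$W[idx])
  )
  dplyr::arrange(out, .data$target, .data$source)
}

#' @export
as.data.frame.socnet <- function(x, ...) as.data.frame(network_edges(x))

#' Insert one random in-link
#'
#' Adds exactly one in-link at `target` from a uniformly chosen, previously
#' unlinked non-self source; the weight is +1 with probability `p_activating`.
#' The returned descriptor is sufficient to undo the change with
#' [revert_link()].
#'
#' @param net a `socnet` object.
#' @param target node id (1-based) receiving the link.
#' @param p_activating probability of drawing an activating (+1) weight.
#' @param seed optional RNG seed.
#' @return A list with elements `network` (the modified `socnet`) and `link`
#'   (the descriptor: `action`, `source`, `target`, `weight`).
#' @export
add_in_link <- function(net, target, p_activating = 0.5, seed = NULL) {
  n <- n_nodes(net)
  target <- check_count(target, "target")
  if (target > n) stop_invalid("`target` out of range.")
  p <- check_prob(p_activating, "p_activating")
  candidates <- which(net$W[target, ] == 0L)
  candidates <- candidates[candidates != target]
  if (length(candidates) == 0L) {
    abort(sprintf("node %d already has in-links from all other nodes.", target),
      class = "socnet_no_candidate"
    )
  }
  with_seed(seed, {
    src <- if (length(candidates) == 1L) candidates else sample(candidates, 1L)
    w <- if (runif(1L) < p) 1L else -1L
    net$W[target, src] <- w
    list(
      network = net,
      link = list(action = "insert", source = src, target = target, weight = w)
    )
  })
}

#' Remove one random in-link
#'
#' Deletes a uniformly chosen existing in-link at `target` and returns a
#' descriptor sufficient to restore it with [revert_link()].
#'
#' @inheritParams add_in_link
#' @return A list with elements `network` and `link` (as in [add_in_link()],
#'   with `action = "remove"`).
#' @export
remove_in_link <- function(net, target, seed = NULL) {
  n <- n_nodes(net)
  target <- check_count(target, "target")
  if (target > n) stop_invalid("`target` out of range.")
  existing <- which(net$W[target, ] != 0L)
  if (length(existing) == 0L) {
    abort(sprintf("node %d has no in-links to remove.", target),
      class = "socnet_no_link"
    )
  }
  with_seed(seed, {
    src <- if (length(existing) == 1L) existing else sample(existing, 1L)
    w <- net$W[target, src]
    net$W[target, src] <- 0L
    list(
      network = net,
      link = list(action = "remove", source = src, target = target, weight = w)
    )
  })
}

#' Undo a single link change
#'
#' Applies the inverse of the operation described by a link descriptor from
#' [add_in_link()] or [remove_in_link()], restoring the network bit-exactly.
#'
#' @param net a `socnet` object.
#' @param link a link descriptor.
#' @return The reverted `socnet`.
#' @export
revert_link <- function(net, link) {
  if (link$action == "insert") {
    net$W[link$target, link$source] <- 0L
  } else if (link$action == "remove") {
    net$W[link$target, link$source] <- link$weight
  } else {
    stop_invalid("unknown link action.")
  }
  net
}

#' Pin the activating-link ratio by flipping random signs
#'
#' Flips the signs of uniformly chosen links, one at a time, until the number
#' of positive links is the integer count whose ratio is closest to
#' `target_ratio`. Link endpoints and the total link count never change.
#'
#' @param net a `socnet` object with at least one link.
#' @param target_ratio desired activating-link ratio in (0, 1].
#' @param seed optional RNG seed.
#' @return The rebalanced `socnet`.
#' @export
rebalance_link_signs <- function(net, target_ratio, seed = NULL) {
  if (!is.numeric(target_ratio) || length(target_ratio) != 1L ||
    is.na(target_ratio) || target_ratio <= 0 || target_ratio > 1) {
    stop_invalid("`target_ratio` must be in (0, 1].")
  }
  l <- n_links(net)
  if (l == 0L) stop_invalid("network has no links to rebalance.")
  pos <- sum(net$W > 0L)
  # nearest achievable positive count given integer link counts
  cand <- unique(pmin(l, pmax(0L, c(floor(target_ratio * l), ceiling(target_ratio * l)))))
  want <- cand[which.min(abs(cand / l - target_ratio))]
  if (want == pos) {
    return(net)
  }
  with_seed(seed, {
    if (want > pos) {
      flippable <- which(net$W < 0L)
      k <- want - pos
      pick <- if (length(flippable) == 1L) flippable else sample(flippable, k)
      net$W[pick] <- 1L
    } else {
      flippable <- which(net$W > 0L)
      k <- pos - want
      pick <- if (length(flippable) == 1L) flippable else sample(flippable, k)
      net$W[pick] <- -1L
    }
    net
  })
}

#' Convert to an igraph object
#'
#' @param net a `socnet` object.
#' @return An `igraph` directed graph with edge attribute `weight` and vertex
#'   attribute `theta`.
#' @export
as_igraph <- function(net) {
  ed <- network_edges(net)
  g <- igraph::graph_from_data_frame(
    data.frame(from = ed$source, to = ed$target, weight = ed$weight),
    directed = TRUE,
    vertices = data.frame(name = seq_len(n_nodes(net)), theta = net$theta)
  )
  g
}
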