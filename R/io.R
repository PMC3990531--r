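#' Read and write network snapshots
#'
#' The snapshot format is a plain TSV edge list `source<TAB>target<TAB>weight`
#' with 0-based node ids, preceded by `#`-prefixed header lines carrying the
#' node count, the per-node thresholds, and (when known) the RNG seed and the
#' adaptation epoch the snapshot was taken at. Writing then reading (or
#' reading then writing) a snapshot is bit-exact: edges are stored in a
#' canonical order (by target, then source).
#'
#' @param net a `socnet` object.
#' @param path file path.
#' @return `write_network_tsv()` returns `path` invisibly;
#'   `read_network_tsv()` returns a `socnet` object.
#' @export
write_network_tsv <- function(net, path) {
  ed <- network_edges(net)
  meta <- net$meta
  fmt_meta <- function(x) {
    if (is.null(x) || length(x) == 0L || is.na(x)) "NA" else as.character(x)
  }
  header <- c(
    "# socnet snapshot",
    sprintf("# n_nodes=%d", n_nodes(net)),
    sprintf("# theta=%s", paste(net$theta, collapse = ",")),
    sprintf("# seed=%s", fmt_meta(meta$seed)),
    sprintf("# epoch=%s", fmt_meta(meta$epoch)),
    "source\ttarget\tweight"
  )
  body <- sprintf("%d\t%d\t%d", ed$source - 1L, ed$target - 1L, ed$weight)
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    ln <- grep(sprintf("^# %s=", key), hdr, value = TRUE)
    if (length(ln) == 0L) {
      return(NULL)
    }
    sub(sprintf("^# %s=", key), "", ln[1L])
  }
  n <- as.integer(get_field("n_nodes"))
  if (is.na(n)) abort("snapshot header is missing n_nodes.", class = "socnet_io_error")
  theta_raw <- get_field("theta")
  theta <- if (is.null(theta_raw)) 0L else as.integer(strsplit(theta_raw, ",")[[1L]])
  parse_meta <- function(x) {
    if (is.null(x) || identical(x, "NA")) NULL else as.numeric(x)
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  stopifnot(identical(body[1L], "source\ttarget\tweight"))
  body <- body[-1L]
  if (length(body) > 0L) {
    parts <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
    edges <- tibble::tibble(
      source = as.integer(parts[, 1L]) + 1L,
      target = as.integer(parts[, 2L]) + 1L,
      weight = as.integer(parts[, 3L])
    )
  } else {
    edges <- NULL
  }
  net <- signed_network(n, edges = edges, theta = theta)
  net$meta$seed <- parse_meta(get_field("seed"))
  net$meta$epoch <- parse_meta(get_field("epoch"))
  net
}

#' @rdname write_network_tsv
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- if (nrow(el) > 0) {
    tibble::tibble(
      source = as.integer(el[, 1L]),
      target = as.integer(el[, 2L]),
      weight = as.integer(igraph::E(g)$weight)
    )
  } else {
    NULL
  }
  theta <- igraph::V(g)$theta
  if (is.null(theta)) theta <- 0L
  signed_network(n, edges = edges, theta = as.integer(theta))
}

#' Export active events as a sparse TSV raster
#'
#' Writes one `t<TAB>node` row (0-based node ids) per node-active event, the
#' sparse event-list convention for spike rasters.
#'
#' @param x either a trajectory matrix (nodes x time, as returned in
#'   `run_window()$trajectory`) or an `avalanche` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(x, path) {
  if (inherits(x, "avalanche")) {
    ev <- x$events
    body <- sprintf("%d\t%d", ev$t, ev$node - 1L)
  } else {
    idx <- which(x != 0L, arr.ind = TRUE)
    idx <- idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
    body <- sprintf("%d\t%d", as.integer(idx[, 2L]), as.integer(idx[, 1L]) - 1L)
  }
  writeLines(c("t\tnode", body), path)
  invisible(path)
}

#' Export avalanche ensemble tables
#'
#' `write_ensemble_summary_tsv()` writes one row per avalanche
#' (`avalanche_id<TAB>S<TAB>T<TAB>terminated_by`);
#' `write_avalanche_events_tsv()` writes the event log of a single avalanche
#' as `avalanche_id<TAB>t<TAB>node`.
#'
#' @param ensemble an `avalanche_ensemble` tibble.
#' @param avalanche an `avalanche` object.
#' @param id avalanche id used in the event log.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_summary_tsv <- function(ensemble, path) {
  body <- sprintf(
    "%d\t%d\t%d\t%s",
    ensemble$avalanche_id, ensemble$S, ensemble$T, ensemble$terminated_by
  )
  writeLines(c("avalanche_id\tS\tT\tterminated_by", body), path)
  invisible(path)
}

#' @rdname write_ensemble_summary_tsv
#' @export
write_avalanche_events_tsv <- function(avalanche, path, id = 1L) {
  ev <- avalanche$events
  body <- sprintf("%d\t%d\t%d", id, ev$t, ev$node - 1L)
  writeLines(c("avalanche_id\tt\tnode", body), path)
  invisible(path)
}
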