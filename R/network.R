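#' Build a directed agonistic network
#'
#' Two flavours are supported: in an initiator-receiver (`"IR"`) network
#' each interaction contributes an edge from initiator to receiver; in a
#' winner-loser (`"WL"`) network each decisive fight contributes an edge
#' from winner to loser. Multiple edges between an ordered pair are
#' aggregated to a single unweighted edge. Every rostered animal is a node,
#' so animals with no interactions remain in the graph as isolated nodes.
#'
#' @param events decisive events of a single pen.
#' @param roster roster of that pen (defines the node set).
#' @param flavor `"IR"` or `"WL"`.
#' @return an `agonistic_network`: list with `flavor`, `nodes` (animal ids,
#'   roster order), `edges` (2-column integer matrix of node indices,
#'   from/to), `adj` and `radj` (forward and reverse adjacency lists).
#' @export
build_network <- function(events, roster, flavor = c("IR", "WL")) {
  flavor <- match.arg(flavor)
  if (nrow(events)) {
    if (!all(events$decisive))
      stop("build_network expects decisive events only", call. = FALSE)
    validate_events(events, roster)
  }
  nodes <- roster$animal_id
  if (flavor == "IR") {
    from <- match(events$initiator, nodes); to <- match(events$receiver, nodes)
  } else {
    from <- match(events$winner, nodes); to <- match(events$loser, nodes)
  }
  edges <- unique(cbind(from = from, to = to))
  if (!nrow(edges)) edges <- matrix(integer(0), 0, 2,
                                    dimnames = list(NULL, c("from", "to")))
  n <- length(nodes)
  adj <- radj <- rep(list(integer(0)), n)
  for (i in seq_len(nrow(edges))) {
    adj[[edges[i, 1L]]] <- c(adj[[edges[i, 1L]]], edges[i, 2L])
    radj[[edges[i, 2L]]] <- c(radj[[edges[i, 2L]]], edges[i, 1L])
  }
  structure(list(flavor = flavor, nodes = nodes, edges = edges,
                 adj = adj, radj = radj),
            class = "agonistic_network")
}

#' @export
print.agonistic_network <- function(x, ...) {
  cat(sprintf("agonistic network (%s): %d nodes, %d aggregated edges, %.0f%% isolated\n",
              x$flavor, length(x$nodes), nrow(x$edges),
              100 * isolated_fraction(x)))
  invisible(x)
}

# BFS geodesic distances from source `s` following `adj`; Inf if unreachable.
bfs_dist <- function(adj, n, s) {
  d <- rep(Inf, n); d[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) for (w in adj[[v]]) if (is.infinite(d[w])) {
      d[w] <- d[v] + 1
      nxt <- c(nxt, w)
    }
    frontier <- nxt
  }
  d
}

#' Degree centrality
#'
#' Raw in/out-degree on the aggregated simple graph and the standardized
#' version `raw / (n - 1)` in `[0, 1]`. In a winner-loser network the raw
#' out-degree equals the number of distinct pen mates beaten.
#'
#' @param net an `agonistic_network`.
#' @return `data.frame` with `animal_id`, `in_degree_raw`, `out_degree_raw`,
#'   `in_degree_std`, `out_degree_std`.
#' @export
degree_centrality <- function(net) {
  n <- length(net$nodes)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  outd <- lengths(net$adj)
  ind <- lengths(net$radj)
  data.frame(animal_id = net$nodes,
             in_degree_raw = as.integer(ind),
             out_degree_raw = as.integer(outd),
             in_degree_std = ind / (n - 1),
             out_degree_std = outd / (n - 1),
             stringsAsFactors = FALSE)
}

#' Closeness centrality with reachable-subset correction
#'
#' On a possibly disconnected digraph, for node `v` let `R` be the set of
#' other nodes connected to `v` by a directed path (towards `v` for the
#' ingoing direction, from `v` for the outgoing direction) and `s` the sum
#' of those geodesic distances. Closeness is `(|R| / s) * (|R| / (n - 1))`:
#' the inverse mean distance over reachable nodes, scaled down by the
#' reachable fraction (Wasserman-Faust correction). Nodes with empty `R`
#' score 0.
#'
#' @param net an `agonistic_network`.
#' @param direction `"in"` (paths towards the node) or `"out"`.
#' @return named numeric vector, one value in `[0, 1]` per node.
#' @export
closeness_centrality <- function(net, direction = c("in", "out")) {
  direction <- match.arg(direction)
  n <- length(net$nodes)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  adj <- if (direction == "in") net$radj else net$adj
  res <- vapply(seq_len(n), function(v) {
    d <- bfs_dist(adj, n, v)[-v]
    d <- d[is.finite(d)]
    if (!length(d)) return(0)
    (length(d) / sum(d)) * (length(d) / (n - 1))
  }, numeric(1))
  names(res) <- net$nodes
  res
}

#' Betweenness centrality (directed, normalized)
#'
#' Fraction of geodesics between ordered pairs `(s, t)`, `s != v != t`,
#' that pass through `v`, with fractional counting over all geodesics and
#' normalization by `(n - 1)(n - 2)`. Computed with Brandes' accumulation
#' algorithm on the unweighted digraph.
#'
#' @param net an `agonistic_network`.
#' @return named numeric vector, one value in `[0, 1]` per node.
#' @export
betweenness_centrality <- function(net) {
  n <- length(net$nodes)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  bc <- numeric(n)
  if (n > 2) {
    for (s in seq_len(n)) {
      # single-source shortest paths with path counts
      dist <- rep(-1L, n); dist[s] <- 0L
      sigma <- numeric(n); sigma[s] <- 1
      preds <- rep(list(integer(0)), n)
      order_visited <- integer(0)
      queue <- s
      while (length(queue)) {
        v <- queue[1L]; queue <- queue[-1L]
        order_visited <- c(order_visited, v)
        for (w in net$adj[[v]]) {
          if (dist[w] < 0L) {
            dist[w] <- dist[v] + 1L
            queue <- c(queue, w)
          }
          if (dist[w] == dist[v] + 1L) {
            sigma[w] <- sigma[w] + sigma[v]
            preds[[w]] <- c(preds[[w]], v)
          }
        }
      }
      delta <- numeric(n)
      for (w in rev(order_visited)) {
        for (v in preds[[w]])
          delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
        if (w != s) bc[w] <- bc[w] + delta[w]
      }
    }
    bc <- bc / ((n - 1) * (n - 2))
  }
  names(bc) <- net$nodes
  bc
}

#' Fraction of isolated nodes
#'
#' An animal is isolated when it has no ingoing and no outgoing edge; such
#' animals have all centralities 0 and no dominance index.
#'
#' @param net an `agonistic_network`.
#' @return proportion in `[0, 1]`.
#' @export
isolated_fraction <- function(net) {
  deg <- lengths(net$adj) + lengths(net$radj)
  mean(deg == 0)
}

#' All five centralities of a network as one table
#'
#' @param net an `agonistic_network`.
#' @return `data.frame` with `animal_id`, raw and standardized in/out
#'   degrees, `closeness_in`, `closeness_out`, `betweenness`.
#' @export
centrality_table <- function(net) {
  deg <- degree_centrality(net)
  deg$closeness_in <- unname(closeness_centrality(net, "in"))
  deg$closeness_out <- unname(closeness_centrality(net, "out"))
  deg$betweenness <- unname(betweenness_centrality(net))
  deg
}

#' Export the aggregated edge list
#'
#' @param net an `agonistic_network`.
#' @param pen_id pen identifier to stamp on each row.
#' @return `data.frame` with `pen_id`, `flavor`, `source`, `target`.
#' @export
edge_list <- function(net, pen_id = NA_character_) {
  data.frame(pen_id = pen_id, flavor = net$flavor,
             source = net$nodes[net$edges[, 1L]],
             target = net$nodes[net$edges[, 2L]],
             stringsAsFactors = FALSE)
}
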