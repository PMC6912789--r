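# Independent brute-force graph oracles, used only to cross-check the
# package's centrality implementations on small digraphs.

# adjacency matrix (0/1, no self-loops) -> Floyd-Warshall distance matrix
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_closeness <- function(A, direction) {
  D <- oracle_distances(A)
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    d <- if (direction == "in") D[-v, v] else D[v, -v]
    d <- d[is.finite(d)]
    if (!length(d)) return(0)
    (length(d) / sum(d)) * (length(d) / (n - 1))
  }, numeric(1))
}

# enumerate all geodesics s -> t by depth-limited DFS; returns matrix of
# interior-node visit counts plus the number of geodesics
oracle_geodesics_through <- function(A, D, s, t) {
  n <- nrow(A)
  target_len <- D[s, t]
  through <- numeric(n)
  total <- 0
  walk <- function(v, len, interior) {
    if (v == t) {
      if (len == target_len) {
        total <<- total + 1
        through[interior] <<- through[interior] + 1
      }
      return(invisible())
    }
    if (len >= target_len) return(invisible())
    for (w in which(A[v, ] == 1))
      if (D[w, t] == target_len - len - 1)
        walk(w, len + 1, if (w == t) interior else c(interior, w))
  }
  if (is.finite(target_len) && s != t) walk(s, 0, integer(0))
  list(through = through, total = total)
}

oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  bc <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || !is.finite(D[s, t])) next
    g <- oracle_geodesics_through(A, D, s, t)
    if (g$total > 0) bc <- bc + g$through / g$total
  }
  if (n > 2) bc / ((n - 1) * (n - 2)) else numeric(n)
}

# build an agonistic_network directly from an adjacency matrix, via events
net_from_adjacency <- function(A, flavor = "WL") {
  n <- nrow(A)
  ids <- sprintf("a%02d", seq_len(n))
  ros <- pen_roster("PO", ids, "custom")
  idx <- which(A == 1, arr.ind = TRUE)
  if (nrow(idx)) {
    ev <- interaction_events("PO", seq_len(nrow(idx)) / 100,
                             initiator = ids[idx[, 1]],
                             receiver = ids[idx[, 2]],
                             winner = ids[idx[, 1]],
                             loser = ids[idx[, 2]])
  } else {
    ev <- interaction_events(character(0), numeric(0), character(0),
                             character(0))
  }
  build_network(ev, ros, flavor)
}

random_adjacency <- function(n, p = NULL) {
  if (is.null(p)) p <- stats::runif(1, 0.1, 0.7)
  A <- matrix(as.integer(stats::runif(n * n) < p), n, n)
  diag(A) <- 0L
  A
}

# all digraphs on n nodes (n small) as adjacency matrices
all_digraphs <- function(n) {
  cells <- which(diag(n) == 0)
  m <- length(cells)
  lapply(seq_len(2^m) - 1L, function(code) {
    A <- matrix(0L, n, n)
    A[cells] <- as.integer(intToBits(code)[seq_len(m)])
    A
  })
}

# Spearman oracle: average ranks then stats::cor on the ranks
oracle_spearman <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}
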