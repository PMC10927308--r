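# Independent brute-force oracles for graph metrics, written directly from
# the defining formulas (no shared code with the package implementation).

# all-pairs shortest paths by repeated breadth-first search over an
# adjacency list
bf_distances <- function(adj) {
  n <- nrow(adj)
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ] != 0))
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0L
    while (length(frontier)) {
      depth <- depth + 1L
      nxt <- unique(unlist(nbrs[frontier]))
      nxt <- nxt[is.infinite(d[s, nxt])]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

bf_nodal_efficiency <- function(adj) {
  n <- nrow(adj)
  d <- bf_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  rowSums(inv) / (n - 1)
}

bf_global_efficiency <- function(adj) mean(bf_nodal_efficiency(adj))

# triangle count around each node by explicit triple enumeration
bf_triangles <- function(adj) {
  n <- nrow(adj)
  t_i <- numeric(n)
  for (i in seq_len(n)) {
    cnt <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      for (h in seq_len(n)) {
        if (h == i || h == j) next
        cnt <- cnt + adj[i, j] * adj[i, h] * adj[j, h]
      }
    }
    t_i[i] <- cnt / 2
  }
  t_i
}

bf_transitivity <- function(adj) {
  k <- rowSums(adj)
  denom <- sum(k * (k - 1))
  if (denom == 0) return(0)
  sum(2 * bf_triangles(adj)) / denom
}

bf_clustering <- function(adj) {
  k <- rowSums(adj)
  t_i <- bf_triangles(adj)
  ifelse(k >= 2, 2 * t_i / (k * (k - 1)), 0)
}

# random symmetric 0/1 adjacency with edge probability p
random_adjacency <- function(n, p) {
  m <- matrix(0, n, n)
  ut <- upper.tri(m)
  m[ut] <- as.numeric(stats::runif(sum(ut)) < p)
  m + t(m)
}

# random symmetric weight matrix in (0, 1)
random_weights <- function(n) {
  m <- matrix(0, n, n)
  ut <- upper.tri(m)
  m[ut] <- stats::runif(sum(ut))
  m + t(m)
}

as_bg <- function(m) structure(m, class = c("binary_graph", "matrix"))
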