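#' Proportional thresholding and binarization
#'
#' Keeps the `k = round(p * n(n-1)/2)` largest upper-triangular weights of a
#' symmetric connectivity matrix, sets them to 1 and everything else to 0,
#' mirroring to the lower triangle. Proportional (rather than absolute)
#' thresholding fixes the edge density so graph metrics are compared across
#' networks of identical connection count. Ties at the cutoff are broken by
#' ascending (row, column) index, which makes the edge set deterministic and
#' nested across thresholds.
#'
#' @param matrix Symmetric weighted matrix, zero diagonal.
#' @param p Fraction of strongest connections to keep, `0 < p <= 1`.
#' @return Binary adjacency matrix (class `binary_graph`).
#' @export
proportional_threshold <- function(matrix, p) {
  m <- unclass(matrix)
  n <- nrow(m)
  if (p <= 0 || p > 1) stop("`p` must lie in (0, 1]", call. = FALSE)
  ut <- which(upper.tri(m))
  k <- floor(p * length(ut) + 0.5)   # round half up, deterministically
  adj <- matrix(0L, n, n, dimnames = dimnames(m))
  if (k == 0L) {
    warning("threshold keeps no edges; returning edgeless graph")
  } else {
    # order by descending weight, ties by ascending linear (row, col) index
    ord <- ut[order(-m[ut], ut)]
    keep <- ord[seq_len(min(k, length(ord)))]
    adj[keep] <- 1L
    adj <- adj + t(adj)
  }
  structure(adj, class = c("binary_graph", "matrix"))
}

as_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(unclass(adj) != 0, mode = "undirected",
                                      diag = FALSE)
}

check_binary_graph <- function(adj) {
  m <- unclass(adj)
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("adjacency must be square", call. = FALSE)
  }
  if (any(m != t(m))) stop("adjacency must be symmetric", call. = FALSE)
  if (any(diag(m) != 0)) stop("diagonal must be zero", call. = FALSE)
  if (!all(m %in% c(0, 1))) stop("entries must be 0/1", call. = FALSE)
  m
}

#' Nodal and global efficiency
#'
#' Efficiency is the mean inverse shortest-path length: for node i,
#' `E_i = sum_{j != i} 1/d_ij / (n - 1)` with `d_ij` the unweighted (BFS)
#' shortest-path length; unreachable pairs contribute zero. Global
#' efficiency is the mean of the nodal values and lies in `[0, 1]`; an
#' edgeless graph has efficiency 0.
#'
#' @param adj Binary adjacency matrix.
#' @return `nodal_efficiency()`: per-node vector; `global_efficiency()`:
#'   scalar.
#' @export
nodal_efficiency <- function(adj) {
  m <- check_binary_graph(adj)
  n <- nrow(m)
  if (n < 2L) return(stats::setNames(numeric(n), rownames(m)))
  d <- igraph::distances(as_igraph(m))
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  stats::setNames(rowSums(inv) / (n - 1), rownames(m))
}

#' @rdname nodal_efficiency
#' @export
global_efficiency <- function(adj) {
  mean(nodal_efficiency(adj))
}

#' Transitivity (collectively normalized triangle density)
#'
#' Ratio of closed triples to connected triples over the whole graph:
#' `T = sum_i 2 t_i / sum_i k_i (k_i - 1)`, with `t_i` the triangle count
#' around node i and `k_i` its degree. Unlike nodal clustering, the
#' normalization is collective, so low-degree nodes cannot dominate. Graphs
#' without any connected triple return 0.
#'
#' @param adj Binary adjacency matrix.
#' @return Scalar in `[0, 1]`.
#' @export
graph_transitivity <- function(adj) {
  m <- check_binary_graph(adj)
  k <- rowSums(m)
  denom <- sum(k * (k - 1))
  if (denom == 0) return(0)
  tri2 <- sum(diag(m %*% m %*% m))    # 6 * number of triangles
  tri2 / denom
}

#' Nodal clustering coefficient
#'
#' Per-node fraction of a node's neighbour pairs that are themselves
#' connected: `C_i = 2 t_i / (k_i (k_i - 1))`; nodes with degree below 2
#' have `C_i = 0`. The network mean is available via `mean()` of the
#' returned vector.
#'
#' @param adj Binary adjacency matrix.
#' @return Named per-node vector in `[0, 1]`.
#' @export
nodal_clustering <- function(adj) {
  m <- check_binary_graph(adj)
  k <- rowSums(m)
  t2 <- diag(m %*% m %*% m)           # 2 t_i per node
  ci <- ifelse(k >= 2, t2 / (k * (k - 1)), 0)
  stats::setNames(ci, rownames(m))
}

#' Node degree
#'
#' @param adj Binary adjacency matrix.
#' @return Named per-node degree vector.
#' @export
node_degree <- function(adj) {
  m <- check_binary_graph(adj)
  stats::setNames(rowSums(m), rownames(m))
}

#' Area under a metric-versus-threshold curve
#'
#' Trapezoidal integral of a graph metric over the proportional-threshold
#' axis, removing the dependence on any single threshold choice. The result
#' carries metric x threshold-fraction units (not normalized by the range
#' width), so a metric bounded in `[0, 1]` over the default 0.05-0.40 sweep
#' has AUC in `[0, 0.35]`.
#'
#' @param thresholds Increasing threshold fractions (>= 2 values).
#' @param values Metric values, same length.
#' @return Scalar AUC.
#' @export
metric_auc <- function(thresholds, values) {
  if (length(thresholds) < 2L) {
    stop("AUC needs at least 2 threshold points", call. = FALSE)
  }
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  trapz(thresholds, values)
}

#' Graph metrics across a proportional-threshold sweep
#'
#' Binarizes the connectivity matrix at each threshold (default 5% to 40% in
#' 1% steps, 36 values) and evaluates the requested metrics. Global metrics
#' yield one curve; nodal metrics yield one curve per channel.
#'
#' @param matrix Symmetric weighted connectivity matrix.
#' @param thresholds Threshold fractions.
#' @param metrics Subset of `"global_efficiency"`, `"transitivity"`,
#'   `"nodal_efficiency"`, `"nodal_clustering"`, `"degree"`.
#' @return List with `thresholds`, `global` (named list of numeric curves)
#'   and `nodal` (named list of node x threshold matrices).
#' @export
threshold_sweep <- function(matrix,
                            thresholds = seq(0.05, 0.40, by = 0.01),
                            metrics = c("global_efficiency", "transitivity",
                                        "nodal_efficiency",
                                        "nodal_clustering")) {
  metrics <- match.arg(metrics, several.ok = TRUE,
                       choices = c("global_efficiency", "transitivity",
                                   "nodal_efficiency", "nodal_clustering",
                                   "degree"))
  n <- nrow(matrix)
  labels <- rownames(matrix)
  glob <- list()
  nodal <- list()
  g_names <- intersect(c("global_efficiency", "transitivity"), metrics)
  n_names <- intersect(c("nodal_efficiency", "nodal_clustering", "degree"),
                       metrics)
  for (gm in g_names) glob[[gm]] <- numeric(length(thresholds))
  for (nm in n_names) {
    nodal[[nm]] <- matrix(0, n, length(thresholds),
                          dimnames = list(labels, NULL))
  }
  for (ti in seq_along(thresholds)) {
    adj <- proportional_threshold(matrix, thresholds[ti])
    need_eff <- any(c("global_efficiency", "nodal_efficiency") %in% metrics)
    if (need_eff) ei <- nodal_efficiency(adj)
    if ("global_efficiency" %in% metrics) {
      glob[["global_efficiency"]][ti] <- mean(ei)
    }
    if ("transitivity" %in% metrics) {
      glob[["transitivity"]][ti] <- graph_transitivity(adj)
    }
    if ("nodal_efficiency" %in% metrics) nodal[["nodal_efficiency"]][, ti] <- ei
    if ("nodal_clustering" %in% metrics) {
      nodal[["nodal_clustering"]][, ti] <- nodal_clustering(adj)
    }
    if ("degree" %in% metrics) nodal[["degree"]][, ti] <- node_degree(adj)
  }
  list(thresholds = thresholds, global = glob, nodal = nodal)
}

#' AUC summaries of a threshold sweep
#'
#' @param sweep Result of [threshold_sweep()].
#' @return List with `global` (named scalars) and `nodal` (named per-node
#'   vectors) of AUC values.
#' @export
sweep_auc <- function(sweep) {
  th <- sweep$thresholds
  list(
    global = lapply(sweep$global, function(v) metric_auc(th, v)),
    nodal = lapply(sweep$nodal, function(m) {
      apply(m, 1L, function(v) metric_auc(th, v))
    })
  )
}
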