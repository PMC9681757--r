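#' Shortest-path census of a binary network
#'
#' Hop-count distances and shortest-path counts between all node pairs,
#' computed by breadth-first search from every node. Unreachable pairs have
#' infinite distance and a path count of 0.
#'
#' @param a symmetric 0/1 adjacency matrix.
#' @return list with `dist` (n x n hop counts, `Inf` for unreachable pairs, 0
#'   on the diagonal) and `sigma` (n x n counts of distinct shortest paths).
#' @export
shortest_path_census <- function(a) {
  check_square_symmetric(a, "a")
  n <- nrow(a)
  d <- igraph::distances(as_graph(a))
  dimnames(d) <- dimnames(a)
  # count shortest paths by dynamic programming over the BFS level structure:
  # sigma(s, v) = sum of sigma(s, u) over predecessors u of v
  sigma <- matrix(0, n, n, dimnames = dimnames(a))
  nbrs <- apply(a > 0, 1, which, simplify = FALSE)
  for (s in seq_len(n)) {
    sig <- numeric(n)
    sig[s] <- 1
    ds <- d[s, ]
    finite <- which(is.finite(ds) & ds > 0)
    for (v in finite[order(ds[finite])]) {
      pred <- nbrs[[v]][ds[nbrs[[v]]] == ds[v] - 1]
      sig[v] <- sum(sig[pred])
    }
    sigma[s, ] <- sig
  }
  list(dist = d, sigma = sigma)
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over all ordered node pairs,
#' `E = 1/(n(n-1)) * sum_{i != j} 1/d(i,j)`, with `1/Inf = 0` for
#' unreachable pairs. Ranges from 0 (empty graph) to 1 (complete graph).
#'
#' @param a symmetric 0/1 adjacency matrix, `n >= 2`.
#' @return scalar in `[0, 1]`.
#' @export
global_efficiency <- function(a) {
  check_square_symmetric(a, "a")
  if (nrow(a) < 2) stop("need at least 2 nodes", call. = FALSE)
  if (sum(a) == 0) return(0)
  igraph::global_efficiency(as_graph(a))
}

#' Nodal clustering coefficient
#'
#' For each node, the fraction of its neighbor pairs that are directly
#' connected: `C_i = 2 t_i / (k_i (k_i - 1))` with `t_i` the number of edges
#' among the neighbors of `i`; nodes of degree < 2 get `C_i = 0`. The network
#' value is the unweighted mean over all nodes.
#'
#' @param a symmetric 0/1 adjacency matrix.
#' @return list with `nodal` (per-node coefficients) and `network` (mean).
#' @export
clustering_coefficient <- function(a) {
  check_square_symmetric(a, "a")
  ci <- igraph::transitivity(as_graph(a), type = "local", isolates = "zero")
  names(ci) <- rownames(a)
  list(nodal = ci, network = mean(ci))
}

#' Betweenness centrality
#'
#' For each node, the number of shortest paths between other node pairs that
#' pass through it, with path multiplicity shared:
#' `B_i = sum_{s != i != t} sigma(s,t | i) / sigma(s,t)` over unordered pairs.
#' Unnormalized by default (rankings are invariant to the normalization).
#'
#' @param a symmetric 0/1 adjacency matrix.
#' @param normalized divide by `(n-1)(n-2)/2` (default FALSE).
#' @return named numeric vector of nodal betweenness values.
#' @export
betweenness_centrality <- function(a, normalized = FALSE) {
  check_square_symmetric(a, "a")
  b <- igraph::betweenness(as_graph(a), directed = FALSE,
                           normalized = normalized)
  names(b) <- rownames(a)
  b
}

#' Flow coefficient
#'
#' For each node, the fraction of its neighbor pairs with no direct edge
#' between them — the pairs whose shortest communication must pass through the
#' node as a length-2 path: `f_i = (# disconnected neighbor pairs) /
#' (k_i (k_i - 1) / 2)`; nodes of degree < 2 get `f_i = 0`. High values mark
#' "local bridges". For binary graphs this is the complement of the clustering
#' coefficient (`f_i + C_i = 1` for `k_i >= 2`), a structural identity used as
#' a cross-check in the test suite; the two are computed independently.
#'
#' @param a symmetric 0/1 adjacency matrix.
#' @return named numeric vector of nodal flow coefficients in `[0, 1]`.
#' @export
flow_coefficient <- function(a) {
  check_square_symmetric(a, "a")
  n <- nrow(a)
  f <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    pairs <- k * (k - 1) / 2
    linked <- sum(a[nb, nb]) / 2
    f[i] <- (pairs - linked) / pairs
  }
  names(f) <- rownames(a)
  f
}

#' Participation coefficient
#'
#' For each node, how evenly its edges are spread over the communities of a
#' partition: `P_i = 1 - sum_m (k_im / k_i)^2` with `k_im` the number of edges
#' from `i` to community `m`. 0 when all edges stay in one community (or the
#' node is isolated), approaching 1 as a fixed degree is spread over more
#' communities. High values mark "connectors" between sub-networks.
#'
#' @param a symmetric 0/1 adjacency matrix.
#' @param membership integer vector assigning every node to a community.
#' @return named numeric vector of nodal participation coefficients in
#'   `[0, 1)`.
#' @export
participation_coefficient <- function(a, membership) {
  check_square_symmetric(a, "a")
  n <- nrow(a)
  if (length(membership) != n || anyNA(membership)) {
    stop("`membership` must assign every node to a community", call. = FALSE)
  }
  k <- rowSums(a)
  p <- numeric(n)
  for (m in unique(membership)) {
    km <- rowSums(a[, membership == m, drop = FALSE])
    p <- p + ifelse(k > 0, (km / pmax(k, 1))^2, 0)
  }
  out <- ifelse(k > 0, 1 - p, 0)
  names(out) <- rownames(a)
  out
}

#' All nodal and network-level graph measures
#'
#' Computes degree, clustering coefficient, flow coefficient, betweenness
#' centrality, and participation coefficient per node, plus global efficiency
#' and mean clustering for the network.
#'
#' @param a symmetric 0/1 adjacency matrix.
#' @param membership community assignment used for the participation
#'   coefficient.
#' @return data.frame (one row per node) with columns `node_id`, `k`, `C`,
#'   `f`, `B`, `P`; attributes `global_efficiency` and `mean_clustering`.
#' @export
nodal_metrics <- function(a, membership) {
  cl <- clustering_coefficient(a)
  out <- data.frame(
    node_id = if (!is.null(rownames(a))) rownames(a) else as.character(seq_len(nrow(a))),
    k = rowSums(a),
    C = cl$nodal,
    f = flow_coefficient(a),
    B = betweenness_centrality(a),
    P = participation_coefficient(a, membership),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "global_efficiency") <- global_efficiency(a)
  attr(out, "mean_clustering") <- cl$network
  out
}
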