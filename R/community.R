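#' Modularity of a partition
#'
#' Newman-Girvan modularity with a resolution parameter:
#' `Q = (1/2m) * sum_ij [a_ij - gamma * k_i k_j / (2m)] * delta(c_i, c_j)`.
#' Works on binary and weighted (non-negative) matrices.
#'
#' @param a symmetric adjacency or weight matrix with at least one edge.
#' @param membership community assignment, one entry per node.
#' @param gamma resolution parameter (default 1).
#' @return scalar modularity in `[-0.5, 1]`.
#' @export
modularity_q <- function(a, membership, gamma = 1) {
  check_square_symmetric(a, "a")
  if (length(membership) != nrow(a) || anyNA(membership)) {
    stop("`membership` must assign every node to a community", call. = FALSE)
  }
  if (sum(a) == 0) stop("modularity is undefined for an edgeless network",
                        call. = FALSE)
  g <- as_graph(a, weights = TRUE)
  igraph::modularity(g, canonical_membership(membership),
                     weights = igraph::E(g)$weight, resolution = gamma)
}

#' Louvain community detection
#'
#' One run of the Louvain greedy multi-level modularity optimization, with the
#' randomized node order driven by `seed`. Accepts binary or weighted
#' (non-negative) symmetric matrices; weighted modularity is optimized when
#' weights are present.
#'
#' @param a symmetric adjacency or weight matrix with at least one edge.
#' @param gamma resolution parameter (default 1).
#' @param seed integer seed; set for a reproducible run.
#' @param level partition level tag (`"participant"` or `"group"`), carried in
#'   the result for bookkeeping.
#' @return object of class `betanet_partition`: list with `membership`
#'   (contiguous integer community ids starting at 1), `q` (modularity of the
#'   returned assignment at `gamma`), `n_communities`, `gamma`, `level`.
#' @export
louvain_partition <- function(a, gamma = 1, seed = NULL, level = "participant") {
  check_square_symmetric(a, "a")
  if (sum(a) == 0) stop("cannot cluster an edgeless network", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  g <- as_graph(a, weights = TRUE)
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight,
                                resolution = gamma)
  mem <- canonical_membership(igraph::membership(cl))
  new_partition(mem, q = modularity_q(a, mem, gamma), gamma = gamma,
                level = level)
}

# Internal fast path: n_runs Louvain memberships with the graph built once.
# Seeds base_seed + 0 ... base_seed + n_runs - 1 drive the randomized runs.
louvain_memberships <- function(a, n_runs, gamma = 1, base_seed = 1L) {
  g <- as_graph(a, weights = TRUE)
  w <- igraph::E(g)$weight
  lapply(seq_len(n_runs) - 1L, function(r) {
    set.seed(base_seed + r)
    canonical_membership(igraph::membership(
      igraph::cluster_louvain(g, weights = w, resolution = gamma)
    ))
  })
}

new_partition <- function(membership, q = NA_real_, gamma = 1,
                          level = "participant") {
  structure(
    list(membership = canonical_membership(membership), q = q,
         n_communities = length(unique(membership)), gamma = gamma,
         level = level),
    class = "betanet_partition"
  )
}

#' @export
print.betanet_partition <- function(x, ...) {
  cat(sprintf("Partition (%s level): %d communities over %d nodes, Q = %.4f\n",
              x$level, x$n_communities, length(x$membership), x$q))
  invisible(x)
}

as_membership_vector <- function(p) {
  if (inherits(p, "betanet_partition")) p$membership else as.integer(p)
}

#' Agreement matrix of a set of partitions
#'
#' `D_ij` = fraction of the partitions that place nodes `i` and `j` in the
#' same community. Diagonal set to 0.
#'
#' @param partitions list of membership vectors or `betanet_partition`
#'   objects over the same node set.
#' @return symmetric n x n matrix with entries in `[0, 1]`.
#' @export
agreement_matrix <- function(partitions) {
  mems <- lapply(partitions, as_membership_vector)
  n <- length(mems[[1]])
  if (!all(vapply(mems, length, 1L) == n)) {
    stop("all partitions must cover the same node set", call. = FALSE)
  }
  d <- matrix(0, n, n)
  for (m in mems) d <- d + outer(m, m, "==")
  d <- d / length(mems)
  diag(d) <- 0
  d
}

#' Consensus partition of many Louvain runs
#'
#' Implements consensus partitioning on the agreement matrix: entries of the
#' co-assignment matrix below `tau` are zeroed, Louvain (weighted modularity)
#' is run `n_runs` times on the thresholded agreement graph, and the procedure
#' iterates on the agreement matrix of those runs until all `n_runs` runs
#' return the identical partition, which is the returned fixed point.
#'
#' @param partitions list of membership vectors or `betanet_partition`
#'   objects (>= 2) over the same node set.
#' @param tau agreement threshold in `[0, 1]` (default 0.5).
#' @param n_runs Louvain runs per iteration (default 1000); runs use seeds
#'   `seed`, `seed + 1`, ... for reproducibility.
#' @param seed base integer seed.
#' @param gamma resolution parameter for the Louvain runs (default 1).
#' @param max_iter iteration cap (default 50).
#' @param graph optional binary network on which to evaluate the modularity of
#'   the consensus partition (otherwise `q` is evaluated on the thresholded
#'   agreement graph).
#' @param level level tag for the returned partition.
#' @return `betanet_partition` (the consensus fixed point) with attribute
#'   `n_iter`, the number of consensus iterations used.
#' @export
consensus_partition <- function(partitions, tau = 0.5, n_runs = 1000,
                                seed = 1L, gamma = 1, max_iter = 50,
                                graph = NULL, level = "participant") {
  if (length(partitions) < 2) {
    stop("need at least 2 partitions", call. = FALSE)
  }
  mems <- lapply(partitions, as_membership_vector)
  canon <- lapply(mems, canonical_membership)
  if (length(unique(canon)) == 1) {
    mem <- canon[[1]]
    q <- if (!is.null(graph)) modularity_q(graph, mem, gamma) else NA_real_
    out <- new_partition(mem, q = q, gamma = gamma, level = level)
    attr(out, "n_iter") <- 0L
    return(out)
  }
  d <- agreement_matrix(mems)
  for (iter in seq_len(max_iter)) {
    dt <- d
    dt[dt < tau] <- 0
    if (sum(dt) == 0) {
      warning("agreement matrix is empty after thresholding at tau = ", tau,
              "; returning the all-singleton partition")
      out <- new_partition(seq_along(mems[[1]]), q = NA_real_, gamma = gamma,
                           level = level)
      attr(out, "n_iter") <- iter
      return(out)
    }
    runs <- louvain_memberships(
      dt, n_runs, gamma = gamma,
      base_seed = salt_seed(seed, "consensus", (iter - 1L) * n_runs)
    )
    if (length(unique(runs)) == 1) {
      mem <- runs[[1]]
      q <- if (!is.null(graph)) modularity_q(graph, mem, gamma)
           else modularity_q(dt, mem, gamma)
      out <- new_partition(mem, q = q, gamma = gamma, level = level)
      attr(out, "n_iter") <- iter
      return(out)
    }
    d <- agreement_matrix(runs)
  }
  stop("consensus partitioning did not converge within ", max_iter,
       " iterations; last agreement matrix had mean off-diagonal agreement ",
       sprintf("%.3f", mean(d[upper.tri(d)])), call. = FALSE)
}

#' Consensus community structure of one network
#'
#' The per-network community workflow: run Louvain `n_runs` times (seeds
#' `seed + 0 ... seed + n_runs - 1`), then apply [consensus_partition()] to
#' the runs. This is the "optimal partition" used for each participant and
#' condition.
#'
#' @param a symmetric binary (or weighted) network matrix.
#' @inheritParams consensus_partition
#' @return `betanet_partition` with `q` evaluated on `a`.
#' @export
network_consensus <- function(a, n_runs = 1000, gamma = 1, tau = 0.5,
                              seed = 1L, max_iter = 50,
                              level = "participant") {
  runs <- louvain_memberships(a, n_runs, gamma = gamma, base_seed = seed)
  consensus_partition(runs, tau = tau, n_runs = n_runs,
                      seed = salt_seed(seed, "network-consensus"),
                      gamma = gamma, max_iter = max_iter, graph = a,
                      level = level)
}

#' Group-representative partition
#'
#' Applies the consensus machinery across participants: the per-participant
#' consensus partitions of one condition are pooled and consensus-partitioned
#' again to a single representative partition for the condition.
#'
#' @param participant_partitions list with one consensus partition per
#'   participant.
#' @inheritParams consensus_partition
#' @return `betanet_partition` at the group level.
#' @export
group_representative <- function(participant_partitions, tau = 0.5,
                                 n_runs = 1000, seed = 1L, gamma = 1,
                                 max_iter = 50, graph = NULL) {
  mems <- lapply(participant_partitions, as_membership_vector)
  agree <- agreement_matrix(mems)
  if (all(agree[upper.tri(agree)] < tau)) {
    warning("participants share no super-threshold agreement; the group ",
            "representative partition is degenerate")
  }
  consensus_partition(participant_partitions, tau = tau, n_runs = n_runs,
                      seed = seed, gamma = gamma, max_iter = max_iter,
                      graph = graph, level = "group")
}

#' Normalized mutual information of two partitions
#'
#' `NMI = 2 I(p1; p2) / (H(p1) + H(p2))` from the community contingency
#' table, in `[0, 1]`: 1 for identical partitions (up to relabeling; two
#' all-in-one-community partitions are identical and give 1), 0 when either
#' partition is a single community while the other is not a deterministic
#' function of it.
#'
#' @param p1,p2 membership vectors or `betanet_partition` objects over the
#'   same node set.
#' @return scalar in `[0, 1]`.
#' @export
nmi <- function(p1, p2) {
  m1 <- as_membership_vector(p1)
  m2 <- as_membership_vector(p2)
  if (length(m1) != length(m2)) {
    stop("partitions must cover the same node set", call. = FALSE)
  }
  n <- length(m1)
  tab <- table(m1, m2) / n
  px <- rowSums(tab)
  py <- colSums(tab)
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  if (hx + hy == 0) return(1)  # both single-community, hence identical
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / (px[row(tab)[nz]] * py[col(tab)[nz]])))
  2 * mi / (hx + hy)
}

#' Label detected communities against a reference partition
#'
#' Assigns each detected community the reference sub-network label with which
#' it has maximal Jaccard overlap (ties broken by larger overlap count, then
#' lexicographic label); communities with no overlap are labeled
#' `"unassigned"`. The full overlap table is returned for review, since
#' labeling that a study would do by visual inspection is automated here.
#'
#' @param partition membership vector or `betanet_partition`.
#' @param reference character vector of reference sub-network labels per node
#'   (`NA` for unassigned nodes); must cover at least `min_coverage` of the
#'   nodes.
#' @param target_node optional node index; when given, the result reports the
#'   label of the community containing it.
#' @param min_coverage minimum fraction of nodes the reference must label
#'   (default 0.8).
#' @return list with `labels` (community id -> label), `overlap` (data.frame
#'   community, label, jaccard, intersection), and `target_label` (NA when
#'   `target_node` is NULL).
#' @export
label_subnetworks <- function(partition, reference, target_node = NULL,
                              min_coverage = 0.8) {
  mem <- as_membership_vector(partition)
  if (length(reference) != length(mem)) {
    stop("`reference` must have one label per node", call. = FALSE)
  }
  coverage <- mean(!is.na(reference))
  if (coverage < min_coverage) {
    stop(sprintf("reference labels cover only %.0f%% of nodes (need >= %.0f%%)",
                 100 * coverage, 100 * min_coverage), call. = FALSE)
  }
  comms <- sort(unique(mem))
  labs <- sort(unique(reference[!is.na(reference)]))
  overlap <- do.call(rbind, lapply(comms, function(cm) {
    in_c <- mem == cm
    do.call(rbind, lapply(labs, function(l) {
      in_l <- !is.na(reference) & reference == l
      inter <- sum(in_c & in_l)
      uni <- sum(in_c | in_l)
      data.frame(community = cm, label = l,
                 jaccard = if (uni > 0) inter / uni else 0,
                 intersection = inter, stringsAsFactors = FALSE)
    }))
  }))
  labels <- vapply(comms, function(cm) {
    o <- overlap[overlap$community == cm, ]
    if (max(o$intersection) == 0) return("unassigned")
    o <- o[order(-o$jaccard, -o$intersection, o$label), ]
    o$label[1]
  }, character(1))
  names(labels) <- as.character(comms)
  target_label <- if (!is.null(target_node)) {
    labels[[as.character(mem[target_node])]]
  } else {
    NA_character_
  }
  list(labels = labels, overlap = overlap, target_label = target_label)
}
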