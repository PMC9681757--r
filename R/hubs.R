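#' Group-level node ranking for one metric
#'
#' Averages a nodal metric over participants and ranks the nodes in descending
#' order of the group mean (rank 1 = largest). Exact ties get deterministic
#' adjacent ranks (broken by node order) and are flagged.
#'
#' @param values participants x nodes numeric matrix of one metric under one
#'   condition; column names are node ids.
#' @return data.frame with `node_id`, `mean`, `rank`, `tie` (TRUE when the
#'   node's mean is shared with another node).
#' @export
rank_nodes <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("missing participant data", call. = FALSE)
  mu <- colMeans(values)
  node_id <- if (!is.null(colnames(values))) colnames(values)
             else as.character(seq_along(mu))
  ord <- order(-mu, seq_along(mu))
  rk <- integer(length(mu))
  rk[ord] <- seq_along(mu)
  data.frame(
    node_id = node_id,
    mean = mu,
    rank = rk,
    tie = duplicated(mu) | duplicated(mu, fromLast = TRUE),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Identify hubs as the top fraction of ranked nodes
#'
#' Nodes ranked within the top `fraction` are hubs; the rank cutoff is
#' `floor(fraction * n)` (263 nodes at 5% gives a cutoff of 13). Ties
#' straddling the cutoff are reported, never silently resolved.
#'
#' @param ranks data.frame from [rank_nodes()].
#' @param fraction top fraction of nodes counted as hubs (default 0.05).
#' @return `ranks` with a logical `hub` column added; attributes `cutoff`
#'   (the hub rank cutoff) and `tie_at_cutoff` (TRUE when the cutoff splits a
#'   group of tied means).
#' @export
identify_hubs <- function(ranks, fraction = 0.05) {
  n <- nrow(ranks)
  if (n < 20) stop("need at least 20 nodes for a meaningful hub fraction",
                   call. = FALSE)
  cutoff <- floor(fraction * n)
  ranks$hub <- ranks$rank <= cutoff
  tie_at_cutoff <- cutoff >= 1 && cutoff < n &&
    ranks$mean[ranks$rank == cutoff] == ranks$mean[ranks$rank == cutoff + 1]
  if (tie_at_cutoff) {
    warning("tied group means straddle the hub cutoff (rank ", cutoff,
            "); hub membership at the boundary is order-determined")
  }
  attr(ranks, "cutoff") <- cutoff
  attr(ranks, "tie_at_cutoff") <- tie_at_cutoff
  ranks
}

#' Classify a node's interface roles across conditions
#'
#' Translates hub flags on the three interface metrics into roles: a flow-
#' coefficient hub is a local bridge (coordinates communication between its
#' neighbors), a betweenness hub is a global bridge (joins shortest paths
#' between remote nodes), and a participation hub is a connector (links
#' different sub-networks).
#'
#' @param hub_flags logical matrix, conditions in rows and metrics `f`, `B`,
#'   `P` in columns: whether the node is a hub by that metric in that
#'   condition.
#' @return list with `roles` (per condition, a character vector drawn from
#'   `local_bridge`, `global_bridge`, `connector`) and `matrix` (the
#'   condition x role logical matrix).
#' @export
classify_roles <- function(hub_flags) {
  hub_flags <- as.matrix(hub_flags)
  if (!all(c("f", "B", "P") %in% colnames(hub_flags))) {
    stop("`hub_flags` needs columns f, B, P", call. = FALSE)
  }
  role_map <- c(f = "local_bridge", B = "global_bridge", P = "connector")
  m <- hub_flags[, names(role_map), drop = FALSE]
  colnames(m) <- unname(role_map)
  roles <- apply(m, 1, function(r) colnames(m)[r], simplify = FALSE)
  list(roles = roles, matrix = m)
}

#' Paired permutation comparison of the target node against every other node
#'
#' For each non-target node, tests whether its metric values are lower than
#' the target node's across participants: the statistic is the mean
#' within-participant difference (target minus comparison), and the null is
#' built by random sign flips of the differences (exhaustive over all `2^n`
#' sign patterns when participants `n <= max_exhaustive`, Monte-Carlo with
#' `n_perm` draws otherwise). One-sided p-values ("comparison < target"),
#' uncorrected.
#'
#' @param values participants x nodes matrix of one metric under one
#'   condition.
#' @param target index or column name of the target node.
#' @param n_perm Monte-Carlo permutations (default 10000).
#' @param seed integer seed for the Monte-Carlo draws.
#' @param max_exhaustive largest `n` for exhaustive sign enumeration
#'   (default 12).
#' @return data.frame with `node_id`, `mean_diff` (target minus node), `p`
#'   (one-sided), and `exhaustive` (logical).
#' @export
target_vs_nodes_permutation <- function(values, target, n_perm = 10000,
                                        seed = 1L, max_exhaustive = 12L) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (n < 1) stop("no participants", call. = FALSE)
  if (is.character(target)) target <- match(target, colnames(values))
  if (is.na(target) || target < 1 || target > ncol(values)) {
    stop("`target` does not name a column of `values`", call. = FALSE)
  }
  others <- setdiff(seq_len(ncol(values)), target)
  d <- values[, target] - values[, others, drop = FALSE]  # n x (nodes-1)

  exhaustive <- 2^n <= max(n_perm, 2^min(n, max_exhaustive)) && n <= max_exhaustive
  if (exhaustive) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    set.seed(salt_seed(seed, "target-vs-nodes"))
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  }
  obs <- colMeans(d)
  perm <- (signs %*% d) / n  # draws x nodes, mean differences under the null
  eps <- 1e-12
  count <- colSums(perm >= rep(obs, each = nrow(perm)) - eps)
  p <- if (exhaustive) count / nrow(signs) else (1 + count) / (1 + n_perm)
  data.frame(
    node_id = if (!is.null(colnames(values))) colnames(values)[others]
              else as.character(others),
    mean_diff = obs,
    p = p,
    exhaustive = exhaustive,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
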