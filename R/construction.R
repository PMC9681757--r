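#' Fisher-z Spearman connectivity from a beta series
#'
#' Computes, for every pair of nodes, the Spearman rank correlation of their
#' trial-wise beta series and applies the Fisher z-transform
#' (`atanh`). Tied trial values receive average ranks. Rank correlations of
#' magnitude 1 (a node being a monotone transform of another) are clipped to
#' `1 - 1e-12` before the transform so every entry stays finite. The diagonal
#' is set to 0.
#'
#' @param b trials x nodes numeric matrix (>= 3 trials, no missing values).
#'   Column names, if present, are carried to the result.
#' @return symmetric nodes x nodes matrix of Fisher-z-transformed Spearman
#'   correlations with zero diagonal.
#' @export
#' @examples
#' b <- matrix(rnorm(80 * 5), 80, 5)
#' w <- beta_correlation(b)
beta_correlation <- function(b) {
  b <- as.matrix(b)
  if (nrow(b) < 3) stop("need at least 3 trials", call. = FALSE)
  if (anyNA(b) || !all(is.finite(b))) {
    stop("beta series contain missing or non-finite values", call. = FALSE)
  }
  sds <- apply(b, 2, sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    nm <- if (!is.null(colnames(b))) colnames(b)[bad] else as.character(bad)
    stop("constant beta series for node(s): ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  r <- cor(b, method = "spearman")
  r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  w <- atanh(r)
  diag(w) <- 0
  w <- (w + t(w)) / 2
  dimnames(w) <- list(colnames(b), colnames(b))
  w
}

#' Proportional threshold of a weighted network
#'
#' Binarizes a weighted connectivity matrix at a target density `d`% by keeping
#' the `m = round(d/100 * n(n-1)/2)` upper-triangle entries with the largest
#' weight as edges (round half up). By default edges are ranked by signed
#' weight (most positive first), the common practice for correlation networks;
#' set `absolute = TRUE` to rank by magnitude. Ties are broken by lexicographic
#' (row, column) order for determinism.
#'
#' @param w symmetric weighted matrix (diagonal ignored).
#' @param density target density in percent, `0 < density < 100`.
#' @param absolute rank edges by `|w|` instead of signed value (default FALSE).
#' @return symmetric 0/1 adjacency matrix with attribute `density`.
#' @export
proportional_threshold <- function(w, density, absolute = FALSE) {
  check_square_symmetric(w, "w")
  if (!(density > 0 && density < 100)) {
    stop("`density` must be in (0, 100)", call. = FALSE)
  }
  n <- nrow(w)
  n_pairs <- n * (n - 1) / 2
  m <- floor(density / 100 * n_pairs + 0.5)  # round half up
  ut <- which(upper.tri(w), arr.ind = TRUE)
  vals <- w[upper.tri(w)]
  ord <- order(-vals, ut[, 1], ut[, 2])
  keep <- ord[seq_len(min(m, n_pairs))]
  a <- matrix(0L, n, n, dimnames = dimnames(w))
  a[ut[keep, , drop = FALSE]] <- 1L
  a <- a + t(a)
  attr(a, "density") <- density
  a
}

#' Size of the largest connected component
#'
#' @param a symmetric 0/1 adjacency matrix.
#' @return the number of nodes in the largest connected component; isolated
#'   nodes count as components of size 1, so an empty graph returns 1.
#' @export
lcc_size <- function(a) {
  check_square_symmetric(a, "a")
  comp <- igraph::components(as_graph(a))
  max(comp$csize)
}

#' Select the analysis density range from connectedness
#'
#' Sweeps candidate densities over an ensemble of weighted networks (all
#' participants x conditions) and picks the range in which the networks are
#' fully connected: the lower bound is the sparsest density at which at least
#' `full_fraction` of the networks have a largest connected component equal to
#' the network size, and the upper bound is the sparsest density at which all
#' of them do.
#'
#' @param networks list of weighted matrices (see [beta_correlation()]).
#' @param densities candidate densities in percent, sorted ascending
#'   (default `15:22`).
#' @param full_fraction fraction of networks required to be fully connected at
#'   the lower bound (default 0.90).
#' @param absolute passed to [proportional_threshold()].
#' @return list with `d_low`, `d_high`, `step`, and `fractions` (the
#'   per-density fraction of fully connected networks).
#' @export
select_density_range <- function(networks, densities = 15:22,
                                 full_fraction = 0.90, absolute = FALSE) {
  if (!length(networks)) stop("no networks supplied", call. = FALSE)
  if (is.unsorted(densities)) {
    stop("`densities` must be sorted ascending", call. = FALSE)
  }
  n <- nrow(networks[[1]])
  frac <- vapply(densities, function(d) {
    mean(vapply(networks, function(w) {
      lcc_size(proportional_threshold(w, d, absolute = absolute)) == n
    }, logical(1)))
  }, numeric(1))
  names(frac) <- as.character(densities)
  i_low <- which(frac >= full_fraction)[1]
  i_high <- which(frac == 1)[1]
  if (is.na(i_low) || is.na(i_high)) {
    stop("no candidate density satisfies the connectedness criterion; ",
         "fully-connected fractions were: ",
         paste(sprintf("%s%%:%.2f", names(frac), frac), collapse = ", "),
         call. = FALSE)
  }
  step <- if (length(densities) > 1) diff(densities)[1] else 1
  list(d_low = densities[i_low], d_high = densities[i_high],
       step = step, fractions = frac)
}

#' Assemble the analysis ROI set from a reference parcellation
#'
#' Reproduces the node bookkeeping used to go from a published reference
#' parcellation to the analysis set: ROIs outside the gray-matter mask are
#' removed, the study-specific target ROI is added, and any reference ROI
#' whose sphere overlaps the target sphere (center distance < `2 * radius`)
#' is removed. With a 264-ROI reference containing one non-gray-matter ROI and
#' one ROI overlapping the target, this yields 263 analysis nodes.
#'
#' @param nodes reference node table as from [make_reference_nodes()]:
#'   columns `node_id`, `x`, `y`, `z`, `label`, `network`, and optionally
#'   `gray_matter` (defaults to all TRUE when absent).
#' @param target_xyz target ROI center coordinates (default
#'   `c(-47, -55, -17)`).
#' @param target_id,target_label identifiers for the added target row.
#' @param target_network sub-network label for the target row (default NA:
#'   to be determined by the community analysis).
#' @param radius ROI sphere radius in mm (default 5).
#' @return node table with the retained reference ROIs plus the target ROI as
#'   the last row; attribute `target_node` gives its row index.
#' @export
assemble_roi_set <- function(nodes, target_xyz = c(-47, -55, -17),
                             target_id = "target", target_label = "target ROI",
                             target_network = NA_character_, radius = 5) {
  need <- c("node_id", "x", "y", "z", "label", "network")
  if (!all(need %in% names(nodes))) {
    stop("node table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(nodes$gray_matter)) nodes$gray_matter <- TRUE
  kept <- nodes[nodes$gray_matter, , drop = FALSE]
  d <- sqrt((kept$x - target_xyz[1])^2 + (kept$y - target_xyz[2])^2 +
            (kept$z - target_xyz[3])^2)
  kept <- kept[d >= 2 * radius, , drop = FALSE]
  target_row <- data.frame(
    node_id = target_id, x = target_xyz[1], y = target_xyz[2],
    z = target_xyz[3], label = target_label, network = target_network,
    gray_matter = TRUE, stringsAsFactors = FALSE
  )
  out <- rbind(kept[names(target_row)], target_row)
  rownames(out) <- NULL
  attr(out, "target_node") <- nrow(out)
  out
}
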