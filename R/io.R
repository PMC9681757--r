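#' Read a beta-series matrix from delimited text
#'
#' Reads a trials x nodes matrix written with a header row of node ids
#' (tab-delimited). Validates that every cell is numeric and non-missing and,
#' when `node_ids` is given, that the header matches it exactly. A blank
#' trailing line is accepted.
#'
#' @param path file path.
#' @param node_ids optional expected node ids, in order.
#' @return numeric matrix with node ids as column names; attribute `n_trials`
#'   records the row count.
#' @export
read_beta_matrix <- function(path, node_ids = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.delim(path, check.names = FALSE, blank.lines.skip = TRUE)
  b <- as.matrix(df)
  if (!is.numeric(b)) {
    bad <- names(df)[!vapply(df, is.numeric, logical(1))]
    stop("non-numeric cells in ", path, " (column(s): ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  if (anyNA(b)) {
    stop("missing values in ", path, " (first at row ",
         which(rowSums(is.na(b)) > 0)[1], ")", call. = FALSE)
  }
  if (!is.null(node_ids) && !identical(colnames(b), as.character(node_ids))) {
    mism <- which(colnames(b) != as.character(node_ids))[1]
    stop("header of ", path, " does not match the node table (first mismatch ",
         "at column ", mism, ": '", colnames(b)[mism], "' vs '",
         node_ids[mism], "')", call. = FALSE)
  }
  attr(b, "n_trials") <- nrow(b)
  b
}

#' Write a beta-series (or any node-columned) matrix as delimited text
#'
#' @param b numeric matrix with node ids as column names.
#' @param path file path.
#' @export
write_beta_matrix <- function(b, path) {
  write.table(b, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write square matrices (weighted or binary networks) as delimited text
#'
#' Square matrices are written with a header row of node ids and no row
#' names; the reader restores symmetric dimnames.
#'
#' @param m square matrix.
#' @param path file path.
#' @export
write_network_matrix <- function(m, path) {
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_matrix
#' @export
read_network_matrix <- function(path) {
  m <- as.matrix(read.delim(path, check.names = FALSE))
  rownames(m) <- colnames(m)
  m
}

#' Read/write a node table (TSV)
#'
#' @param nodes data.frame with at least `node_id`, `x`, `y`, `z`, `label`;
#'   optional `network` and `gray_matter` columns.
#' @param path file path.
#' @export
write_node_table <- function(nodes, path) {
  write.table(nodes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_node_table
#' @export
read_node_table <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read/write a behavior table (TSV)
#'
#' @param behavior data.frame with `participant`, `condition`, `rt`,
#'   `accuracy`.
#' @param path file path.
#' @export
write_behavior <- function(behavior, path) {
  write.table(behavior, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a partition as TSV (node_id, community)
#'
#' @param partition membership vector or `betanet_partition`.
#' @param node_ids node identifiers, in order.
#' @param path file path.
#' @export
write_partition <- function(partition, node_ids, path) {
  mem <- as_membership_vector(partition)
  write.table(
    data.frame(node_id = node_ids, community = mem),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' Writes one beta matrix per participant x condition
#' (`beta_<participant>_<condition>.tsv`, header row of node ids), the node
#' table, the behavior table, and the ground truth (as JSON, with the seed
#' logged).
#'
#' @param cohort a [sample_cohort()] result.
#' @param dir output directory (created if absent).
#' @param nodes optional node table; by default a minimal table is derived
#'   from the cohort's ground truth (module labels as `network`).
#' @return invisibly, the list of files written.
#' @export
write_cohort <- function(cohort, dir, nodes = NULL) {
  stopifnot(inherits(cohort, "betanet_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- cohort$truth
  if (is.null(nodes)) {
    nodes <- data.frame(
      node_id = cohort$node_ids,
      x = 0, y = 0, z = 0,
      label = sprintf("synthetic node %d", seq_len(truth$n_nodes)),
      network = truth$module_labels[truth$partition],
      stringsAsFactors = FALSE
    )
  }
  files <- character(0)
  for (p in names(cohort$beta)) {
    for (cond in truth$conditions) {
      f <- file.path(dir, sprintf("beta_%s_%s.tsv", p, cond))
      write_beta_matrix(cohort$beta[[p]][[cond]], f)
      files <- c(files, f)
    }
  }
  f_nodes <- file.path(dir, "nodes.tsv")
  write_node_table(nodes, f_nodes)
  f_beh <- file.path(dir, "behavior.tsv")
  write_behavior(cohort$behavior, f_beh)
  f_truth <- file.path(dir, "ground_truth.json")
  truth_json <- unclass(truth)
  truth_json$role_profile <- as.data.frame(truth$role_profile)
  jsonlite::write_json(truth_json, f_truth, auto_unbox = TRUE, digits = NA)
  invisible(c(files, f_nodes, f_beh, f_truth))
}
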