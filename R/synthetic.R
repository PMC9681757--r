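#' Ground truth for a synthetic beta-series cohort
#'
#' Defines the planted structure a synthetic cohort is drawn from: a modular
#' partition of the nodes, the within/between-module beta-series correlations,
#' a designated target node (emulating an interface region such as the left
#' ventral occipito-temporal cortex) whose connectivity layout varies by
#' condition, and a planted behavioral correlation.
#'
#' The condition design emulates a spoken-language study: a resting baseline
#' plus perception (PN) and comprehension (CN) tasks, each without (-) or with
#' (+) babble noise. The default role profile makes the target node a member of
#' the fronto-parietal-like module at baseline, a connector anchored in the
#' visual-like module during perception (PN-, PN+), a connector anchored in the
#' sensorimotor-auditory-like module in quiet comprehension (CN-), and a
#' non-connector concentrated in the visual-like module in noisy comprehension
#' (CN+).
#'
#' @param n_nodes number of nodes (default 263).
#' @param module_sizes integer vector of module sizes summing to `n_nodes`
#'   (default `c(66, 66, 66, 65)`, four modules).
#' @param module_labels labels for the modules, used in node tables and
#'   sub-network labeling (default `c("VN", "FPN", "DMN", "SAN")`).
#' @param target_node index of the target node (default 1, the first node of
#'   module 1).
#' @param role_profile conditions x modules matrix; row `c` gives the fraction
#'   of the target node's strong connections placed in each module under
#'   condition `c`. Rows must sum to 1. Default as described above.
#' @param rho_in within-module beta-series correlation, in (0, 1). Default 0.4.
#' @param rho_out between-module correlation, `0 <= rho_out < rho_in`.
#'   Default 0.05.
#' @param n_trials trials per condition (default 80).
#' @param n_participants cohort size (default 24).
#' @param behavior_r named vector of planted Pearson correlations between the
#'   target node's participation coefficient and reaction time, one per task
#'   condition. Default -0.47 in `CN+`, 0 elsewhere.
#' @param mean_rt,sd_rt named vectors of reaction-time means and SDs (ms) per
#'   task condition. Defaults: means 1296/1413/2389/2575 ms, SD 200 ms.
#' @param mean_accuracy named vector of mean accuracies (proportion correct)
#'   per task condition. Default 0.96/0.92/0.88/0.63.
#' @param seed integer seed for cohort sampling.
#' @return an object of class `betanet_truth`: a list with the fields above
#'   plus `partition` (node -> module index) and `conditions`.
#' @seealso [sample_cohort()], [build_block_correlation()]
#' @export
#' @examples
#' truth <- ground_truth(n_nodes = 20, module_sizes = c(5, 5, 5, 5),
#'                       n_participants = 4, seed = 1)
#' table(truth$partition)
ground_truth <- function(n_nodes = 263,
                         module_sizes = c(66L, 66L, 66L, 65L),
                         module_labels = c("VN", "FPN", "DMN", "SAN"),
                         target_node = 1L,
                         role_profile = NULL,
                         rho_in = 0.4,
                         rho_out = 0.05,
                         n_trials = 80L,
                         n_participants = 24L,
                         behavior_r = c("PN-" = 0, "PN+" = 0,
                                        "CN-" = 0, "CN+" = -0.47),
                         mean_rt = c("PN-" = 1296, "PN+" = 1413,
                                     "CN-" = 2389, "CN+" = 2575),
                         sd_rt = c("PN-" = 200, "PN+" = 200,
                                   "CN-" = 200, "CN+" = 200),
                         mean_accuracy = c("PN-" = 0.96, "PN+" = 0.92,
                                           "CN-" = 0.88, "CN+" = 0.63),
                         seed = 1L) {
  n_modules <- length(module_sizes)
  if (sum(module_sizes) != n_nodes) {
    stop("`module_sizes` must sum to `n_nodes`", call. = FALSE)
  }
  if (any(module_sizes < 3)) stop("module sizes must be >= 3", call. = FALSE)
  if (length(module_labels) != n_modules) {
    stop("`module_labels` must have one label per module", call. = FALSE)
  }
  if (!(rho_in > 0 && rho_in < 1)) stop("`rho_in` must be in (0, 1)", call. = FALSE)
  if (!(rho_out >= 0 && rho_out < rho_in)) {
    stop("need 0 <= rho_out < rho_in", call. = FALSE)
  }
  if (n_trials < 3) stop("`n_trials` must be >= 3", call. = FALSE)

  conditions <- BETANET_CONDITIONS
  if (is.null(role_profile)) {
    if (n_modules != 4) {
      stop("supply `role_profile` explicitly when not using 4 modules",
           call. = FALSE)
    }
    role_profile <- rbind(
      "baseline" = c(0.10, 0.70, 0.10, 0.10),  # member of FPN-like module
      "PN-"      = c(0.40, 0.20, 0.20, 0.20),  # connector anchored in VN
      "PN+"      = c(0.40, 0.20, 0.20, 0.20),
      "CN-"      = c(0.20, 0.20, 0.20, 0.40),  # connector anchored in SAN
      "CN+"      = c(0.70, 0.10, 0.10, 0.10)   # concentrated in VN
    )
    colnames(role_profile) <- module_labels
  }
  role_profile <- as.matrix(role_profile)
  if (!all(rownames(role_profile) %in% conditions) ||
      nrow(role_profile) != length(conditions)) {
    stop("`role_profile` must have one row per condition: ",
         paste(conditions, collapse = ", "), call. = FALSE)
  }
  role_profile <- role_profile[conditions, , drop = FALSE]
  if (ncol(role_profile) != n_modules) {
    stop("`role_profile` must have one column per module", call. = FALSE)
  }
  if (any(role_profile < 0) ||
      any(abs(rowSums(role_profile) - 1) > 1e-8)) {
    stop("`role_profile` rows must be non-negative and sum to 1", call. = FALSE)
  }
  task_conditions <- setdiff(conditions, "baseline")
  for (nm in c("behavior_r", "mean_rt", "sd_rt", "mean_accuracy")) {
    v <- get(nm)
    if (!all(task_conditions %in% names(v))) {
      stop(sprintf("`%s` must be named with the task conditions", nm),
           call. = FALSE)
    }
  }
  if (any(abs(behavior_r) > 1)) stop("|behavior_r| must be <= 1", call. = FALSE)
  if (target_node < 1 || target_node > n_nodes) {
    stop("`target_node` out of range", call. = FALSE)
  }

  partition <- rep(seq_len(n_modules), module_sizes)
  structure(
    list(
      n_nodes = as.integer(n_nodes),
      module_sizes = as.integer(module_sizes),
      module_labels = module_labels,
      partition = as.integer(partition),
      target_node = as.integer(target_node),
      conditions = conditions,
      role_profile = role_profile,
      rho_in = rho_in,
      rho_out = rho_out,
      n_trials = as.integer(n_trials),
      n_participants = as.integer(n_participants),
      behavior_r = behavior_r[task_conditions],
      mean_rt = mean_rt[task_conditions],
      sd_rt = sd_rt[task_conditions],
      mean_accuracy = mean_accuracy[task_conditions],
      seed = as.integer(seed)
    ),
    class = "betanet_truth"
  )
}

#' @export
print.betanet_truth <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort ground truth: %d nodes in %d modules (%s),\n  %d participants x %d conditions x %d trials; rho_in=%.2f rho_out=%.2f;\n  target node %d; seed %d\n",
    x$n_nodes, length(x$module_sizes),
    paste(x$module_sizes, collapse = "/"),
    x$n_participants, length(x$conditions), x$n_trials,
    x$rho_in, x$rho_out, x$target_node, x$seed
  ))
  invisible(x)
}

#' Block correlation matrix for one condition
#'
#' Builds the population correlation matrix the beta series of one condition
#' are drawn from: `rho_in` within modules, `rho_out` between modules, unit
#' diagonal, except for the target node whose off-diagonal entries follow the
#' condition's role profile — a budget of strong (`rho_in`-level) connections
#' equal to its module size minus one, distributed over modules in the
#' profile's proportions; all its other entries are `rho_out`. The result is
#' repaired to the nearest positive semidefinite correlation matrix by clipping
#' negative eigenvalues at zero and re-normalizing the diagonal.
#'
#' @param truth a [ground_truth()] object.
#' @param condition one of `truth$conditions`.
#' @return a symmetric `n_nodes` x `n_nodes` correlation matrix.
#' @export
build_block_correlation <- function(truth, condition) {
  stopifnot(inherits(truth, "betanet_truth"))
  if (!condition %in% truth$conditions) {
    stop("unknown condition: ", condition, call. = FALSE)
  }
  part <- truth$partition
  n <- truth$n_nodes
  r <- matrix(truth$rho_out, n, n)
  same <- outer(part, part, "==")
  r[same] <- truth$rho_in
  diag(r) <- 1

  tn <- truth$target_node
  profile <- truth$role_profile[condition, ]
  # strong-connection budget: what an ordinary node of this module would have
  k_strong <- truth$module_sizes[part[tn]] - 1L
  counts <- round(profile * k_strong)
  # largest-remainder fixup so the counts sum exactly to the budget
  while (sum(counts) != k_strong) {
    resid <- profile * k_strong - counts
    j <- if (sum(counts) < k_strong) which.max(resid) else which.min(resid)
    counts[j] <- counts[j] + sign(k_strong - sum(counts))
  }
  row_t <- rep(truth$rho_out, n)
  for (m in seq_along(counts)) {
    cand <- setdiff(which(part == m), tn)
    if (counts[m] > length(cand)) {
      stop("role profile places more strong connections in module ", m,
           " than it has nodes", call. = FALSE)
    }
    row_t[head(cand, counts[m])] <- truth$rho_in
  }
  r[tn, ] <- row_t
  r[, tn] <- row_t
  diag(r) <- 1
  repair_psd(r)
}

#' Repair a symmetric matrix to the nearest positive semidefinite correlation
#' matrix by eigenvalue clipping
#'
#' Negative eigenvalues are clipped at zero, the matrix is reconstructed, and
#' the diagonal is re-normalized to 1. Matrices already positive semidefinite
#' (smallest eigenvalue >= `-tol`) are returned unchanged apart from exact
#' symmetrization.
#'
#' @param r symmetric matrix with unit diagonal.
#' @param tol eigenvalue tolerance (default 1e-8).
#' @keywords internal
repair_psd <- function(r, tol = 1e-8) {
  r <- (r + t(r)) / 2
  e <- eigen(r, symmetric = TRUE)
  if (min(e$values) >= -tol) return(r)
  lam <- pmax(e$values, 0)
  r2 <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(diag(r2))
  if (any(d <= 0)) {
    stop("matrix not repairable to a positive semidefinite correlation matrix",
         call. = FALSE)
  }
  r2 <- r2 / tcrossprod(d)
  r2 <- (r2 + t(r2)) / 2
  diag(r2) <- 1
  if (min(eigen(r2, symmetric = TRUE, only.values = TRUE)$values) < -tol) {
    stop("eigenvalue clipping failed to produce a positive semidefinite matrix",
         call. = FALSE)
  }
  r2
}

#' Sample a synthetic cohort of beta series
#'
#' Draws, for every participant and condition, an `n_trials` x `n_nodes`
#' matrix of trial-wise beta estimates from a zero-mean multivariate normal
#' with the condition's block correlation (see [build_block_correlation()]);
#' draws are independent across participants. Beta series are zero-mean by
#' design: the downstream analysis uses only rank correlations across trials,
#' so mean activation levels are irrelevant.
#'
#' Reaction times are planted against the target node's participation
#' coefficient: for each task condition with a nonzero `behavior_r`, the
#' realized participation of the target node is computed per participant (beta
#' correlation, proportional threshold at `density`, participation against the
#' planted partition) and [generate_behavior()] draws reaction times with the
#' planted population correlation. Conditions with `behavior_r = 0` get
#' independent Gaussian reaction times. Accuracies are Gaussian around the
#' condition means, truncated to [0, 1].
#'
#' @param truth a [ground_truth()] object; its `seed` drives all draws.
#' @param density proportional density (%) used when computing the realized
#'   participation the behavior is planted against (default 15).
#' @return an object of class `betanet_cohort`: list with `beta` (nested list
#'   `beta[[participant]][[condition]]`), `behavior` (data.frame with
#'   participant, condition, rt, accuracy), `node_ids`, and `truth`.
#' @export
sample_cohort <- function(truth, density = 15) {
  stopifnot(inherits(truth, "betanet_truth"))
  n <- truth$n_nodes
  node_ids <- sprintf("n%03d", seq_len(n))

  # one factor per condition: R = F F'  with F = U sqrt(lambda)
  factors <- lapply(truth$conditions, function(cond) {
    r <- build_block_correlation(truth, cond)
    e <- eigen(r, symmetric = TRUE)
    e$vectors %*% diag(sqrt(pmax(e$values, 0)))
  })
  names(factors) <- truth$conditions

  beta <- vector("list", truth$n_participants)
  for (p in seq_len(truth$n_participants)) {
    beta[[p]] <- lapply(truth$conditions, function(cond) {
      set.seed(salt_seed(truth$seed, paste0("beta:", cond), p))
      z <- matrix(rnorm(truth$n_trials * n), truth$n_trials, n)
      x <- z %*% t(factors[[cond]])
      colnames(x) <- node_ids
      x
    })
    names(beta[[p]]) <- truth$conditions
  }
  names(beta) <- sprintf("sub%02d", seq_len(truth$n_participants))

  task_conditions <- names(truth$behavior_r)
  behavior <- do.call(rbind, lapply(task_conditions, function(cond) {
    r_target <- truth$behavior_r[[cond]]
    if (r_target != 0) {
      particip <- vapply(seq_len(truth$n_participants), function(p) {
        w <- beta_correlation(beta[[p]][[cond]])
        a <- proportional_threshold(w, density)
        participation_coefficient(a, truth$partition)[truth$target_node]
      }, numeric(1))
    } else {
      # uncorrelated conditions need no participation anchor
      particip <- rep(0, truth$n_participants)
    }
    rt <- generate_behavior(
      particip, r_target = r_target,
      mean_rt = truth$mean_rt[[cond]], sd_rt = truth$sd_rt[[cond]],
      seed = salt_seed(truth$seed, paste0("rt:", cond))
    )
    set.seed(salt_seed(truth$seed, paste0("acc:", cond)))
    acc <- pmin(1, pmax(0, rnorm(truth$n_participants,
                                 truth$mean_accuracy[[cond]], 0.05)))
    data.frame(
      participant = names(beta),
      condition = cond,
      rt = rt,
      accuracy = acc,
      stringsAsFactors = FALSE
    )
  }))
  rownames(behavior) <- NULL

  structure(
    list(beta = beta, behavior = behavior, node_ids = node_ids, truth = truth),
    class = "betanet_cohort"
  )
}

#' @export
print.betanet_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d participants x %d conditions, %d trials x %d nodes each\n",
    length(x$beta), length(x$truth$conditions),
    x$truth$n_trials, x$truth$n_nodes
  ))
  invisible(x)
}

#' Generate reaction times with a planted correlation
#'
#' Draws a reaction-time vector whose population Pearson correlation with the
#' supplied participation values equals `r_target`:
#' `rt = mean_rt + sd_rt * (r * z + sqrt(1 - r^2) * e)` with `z` the
#' standardized participation and `e` independent standard normal noise.
#'
#' @param participation numeric vector of per-participant values.
#' @param r_target planted Pearson correlation, in `[-1, 1]`.
#' @param mean_rt,sd_rt reaction-time mean and SD in ms.
#' @param seed integer seed.
#' @return numeric vector of reaction times (ms), same length as
#'   `participation`.
#' @export
generate_behavior <- function(participation, r_target, mean_rt = 2000,
                              sd_rt = 200, seed = 1L) {
  n <- length(participation)
  if (n < 3) stop("need at least 3 participants", call. = FALSE)
  if (abs(r_target) > 1) stop("|r_target| must be <= 1", call. = FALSE)
  if (r_target != 0 && sd(participation) == 0) {
    stop("participation has zero variance; cannot plant a nonzero correlation",
         call. = FALSE)
  }
  z <- if (sd(participation) > 0) {
    (participation - mean(participation)) / sd(participation)
  } else {
    rep(0, n)
  }
  set.seed(seed)
  e <- rnorm(n)
  mean_rt + sd_rt * (r_target * z + sqrt(1 - r_target^2) * e)
}

#' Synthetic reference ROI table
#'
#' Builds a synthetic stand-in for a published 264-ROI parcellation: spherical
#' ROIs (5 mm radius) scattered around four module centroids, with one ROI
#' flagged as lying outside the gray-matter mask and one ROI placed so that it
#' overlaps the default target ROI location. All coordinates are synthetic;
#' they emulate the bookkeeping of a real parcellation, not its anatomy.
#'
#' @param n number of reference ROIs (default 264).
#' @param module_sizes module sizes summing to `n` (default `c(66, 66, 67, 65)`).
#' @param module_labels module labels (default VN/FPN/DMN/SAN).
#' @param target_xyz coordinates of the target ROI that [assemble_roi_set()]
#'   will add (default `c(-47, -55, -17)`); one reference ROI is placed 5.7 mm
#'   away so that their 5 mm spheres overlap.
#' @param seed integer seed for the coordinate jitter.
#' @return data.frame with columns `node_id`, `x`, `y`, `z`, `label`,
#'   `network`, `gray_matter`.
#' @export
make_reference_nodes <- function(n = 264L,
                                 module_sizes = c(66L, 66L, 67L, 65L),
                                 module_labels = c("VN", "FPN", "DMN", "SAN"),
                                 target_xyz = c(-47, -55, -17),
                                 seed = 1L) {
  stopifnot(sum(module_sizes) == n, length(module_labels) == length(module_sizes))
  set.seed(salt_seed(seed, "reference-nodes"))
  centroids <- rbind(c(0, -80, 5), c(40, 30, 35), c(0, 50, 20), c(-45, -20, 50))
  centroids <- centroids[rep_len(seq_len(nrow(centroids)), length(module_sizes)), ,
                         drop = FALSE]
  network <- rep(module_labels, module_sizes)
  xyz <- centroids[rep(seq_along(module_sizes), module_sizes), , drop = FALSE] +
    matrix(rnorm(3 * n, 0, 18), n, 3)
  nodes <- data.frame(
    node_id = sprintf("ref%03d", seq_len(n)),
    x = round(xyz[, 1], 1), y = round(xyz[, 2], 1), z = round(xyz[, 3], 1),
    label = sprintf("synthetic region %d", seq_len(n)),
    network = network,
    gray_matter = TRUE,
    stringsAsFactors = FALSE
  )
  # one ROI outside the gray-matter mask (emulating a subcortical exclusion)
  nodes$x[n - 1L] <- 9; nodes$y[n - 1L] <- -4; nodes$z[n - 1L] <- 6
  nodes$label[n - 1L] <- "synthetic non-gray-matter region"
  nodes$gray_matter[n - 1L] <- FALSE
  # one ROI whose 5 mm sphere overlaps the target ROI location
  nodes$x[n] <- target_xyz[1]
  nodes$y[n] <- target_xyz[2] + 4
  nodes$z[n] <- target_xyz[3] + 4
  nodes$label[n] <- "synthetic region overlapping target"
  nodes$network[n] <- module_labels[1]
  nodes
}
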