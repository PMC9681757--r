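#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis with the study defaults:
#' Louvain at resolution 1 run 1000 times per network, consensus threshold
#' 0.5, candidate densities 15-22% in 1% steps, top-5% hubs, and 10000
#' permutations.
#'
#' @param truth a [ground_truth()] object describing the synthetic cohort to
#'   analyse (used when `cohort` is NULL).
#' @param cohort optionally, an existing [sample_cohort()] result (or a cohort
#'   loaded from disk with the same structure).
#' @param densities candidate densities (%) for the connectedness sweep.
#' @param primary_density density at which nodal results are reported; NULL
#'   (default) uses the selected lower bound, where connection noise is
#'   minimal.
#' @param full_fraction fraction of networks required fully connected at the
#'   lower bound (default 0.90).
#' @param gamma Louvain resolution (default 1).
#' @param n_louvain Louvain runs per network (default 1000).
#' @param tau consensus agreement threshold (default 0.5).
#' @param consensus_max_iter consensus iteration cap (default 50).
#' @param hub_fraction top fraction of ranked nodes counted as hubs
#'   (default 0.05).
#' @param n_perm permutations for the condition tests (default 10000).
#' @param seed integer master seed; every stage draws from a stream salted
#'   with the stage name.
#' @param out_dir optional directory; when given, [run_pipeline()] writes all
#'   artifacts there.
#' @return object of class `betanet_config`.
#' @export
pipeline_config <- function(truth = ground_truth(),
                            cohort = NULL,
                            densities = 15:22,
                            primary_density = NULL,
                            full_fraction = 0.90,
                            gamma = 1,
                            n_louvain = 1000,
                            tau = 0.5,
                            consensus_max_iter = 50,
                            hub_fraction = 0.05,
                            n_perm = 10000,
                            seed = 1L,
                            out_dir = NULL) {
  stopifnot(is.null(cohort) || inherits(cohort, "betanet_cohort"))
  if (!(tau >= 0 && tau <= 1)) stop("`tau` must be in [0, 1]", call. = FALSE)
  if (!(hub_fraction > 0 && hub_fraction < 1)) {
    stop("`hub_fraction` must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(truth = truth, cohort = cohort, densities = densities,
         primary_density = primary_density, full_fraction = full_fraction,
         gamma = gamma, n_louvain = n_louvain, tau = tau,
         consensus_max_iter = consensus_max_iter,
         hub_fraction = hub_fraction, n_perm = n_perm,
         seed = as.integer(seed), out_dir = out_dir),
    class = "betanet_config"
  )
}

#' Run the full beta-series network analysis
#'
#' Executes the analysis sequence end to end on a synthetic (or supplied)
#' cohort: beta-series correlation networks, density-range selection from
#' largest-connected-component behavior, proportional thresholding at the
#' primary density, per-network Louvain + consensus partitions, nodal and
#' global graph measures (participation computed against each participant's
#' own consensus partition), group-representative partitions with sub-network
#' labeling against the planted (or supplied) reference, target-node hub
#' ranking and role classification per condition, repeated-measures and
#' pairwise permutation tests, and the brain-behavior correlation. The run is
#' deterministic given the config seed.
#'
#' @param config a [pipeline_config()].
#' @return a report bundle (list) with elements `density`, `partitions`,
#'   `metrics`, `global_table`, `hubs`, `roles`, `subnetworks`, `stats`,
#'   `behavior`, and `manifest`. When `config$out_dir` is set, all artifacts
#'   are also written there (delimited matrices, TSV tables, JSON reports,
#'   and a run manifest).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "betanet_config"))
  cohort <- if (!is.null(config$cohort)) config$cohort else
    sample_cohort(config$truth,
                  density = if (is.null(config$primary_density))
                    min(config$densities) else config$primary_density)
  truth <- cohort$truth
  conditions <- truth$conditions
  task_conditions <- setdiff(conditions, "baseline")
  participants <- names(cohort$beta)
  n <- truth$n_nodes

  ## --- construction -------------------------------------------------------
  weighted <- lapply(participants, function(p) {
    lapply(cohort$beta[[p]], beta_correlation)
  })
  names(weighted) <- participants
  flat <- unlist(weighted, recursive = FALSE)
  density <- select_density_range(flat, config$densities,
                                  full_fraction = config$full_fraction)
  d_primary <- if (is.null(config$primary_density)) density$d_low
               else config$primary_density

  binary <- lapply(weighted, function(ws) {
    lapply(ws, proportional_threshold, density = d_primary)
  })

  ## --- communities and metrics per participant x condition ----------------
  partitions <- list()
  metrics <- list()
  for (p in participants) {
    partitions[[p]] <- list()
    metrics[[p]] <- list()
    for (cond in conditions) {
      a <- binary[[p]][[cond]]
      cons <- network_consensus(
        a, n_runs = config$n_louvain, gamma = config$gamma, tau = config$tau,
        seed = salt_seed(config$seed, paste0("louvain:", p, ":", cond)),
        max_iter = config$consensus_max_iter
      )
      partitions[[p]][[cond]] <- cons
      metrics[[p]][[cond]] <- nodal_metrics(a, cons$membership)
    }
  }

  ## --- group-representative partitions and sub-network labels -------------
  reference <- truth$module_labels[truth$partition]
  group <- list(); subnetworks <- list()
  for (cond in conditions) {
    gp <- group_representative(
      lapply(partitions, `[[`, cond), tau = config$tau,
      n_runs = config$n_louvain,
      seed = salt_seed(config$seed, paste0("group:", cond)),
      gamma = config$gamma, max_iter = config$consensus_max_iter
    )
    group[[cond]] <- gp
    subnetworks[[cond]] <- label_subnetworks(gp, reference,
                                             target_node = truth$target_node)
  }

  ## --- global measures table ----------------------------------------------
  global_measures <- c("E", "meanC", "Q", "n_communities")
  global_table <- lapply(global_measures, function(m) {
    tab <- sapply(conditions, function(cond) {
      vapply(participants, function(p) {
        switch(m,
          E = attr(metrics[[p]][[cond]], "global_efficiency"),
          meanC = attr(metrics[[p]][[cond]], "mean_clustering"),
          Q = partitions[[p]][[cond]]$q,
          n_communities = as.numeric(partitions[[p]][[cond]]$n_communities)
        )
      }, numeric(1))
    })
    rownames(tab) <- participants
    tab
  })
  names(global_table) <- global_measures

  ## --- hubs and roles ------------------------------------------------------
  nodal_names <- c(f = "f", B = "B", P = "P")
  nodal_values <- lapply(nodal_names, function(m) {
    lapply(conditions, function(cond) {
      v <- t(vapply(participants,
                    function(p) metrics[[p]][[cond]][[m]], numeric(n)))
      colnames(v) <- cohort$node_ids
      v
    }) |> setNames(conditions)
  })
  hub_flags <- matrix(FALSE, length(task_conditions), 3,
                      dimnames = list(task_conditions, names(nodal_names)))
  hubs <- list(); target_ranks <- hub_flags
  comparisons <- list()
  for (cond in task_conditions) {
    hubs[[cond]] <- list()
    comparisons[[cond]] <- list()
    for (m in names(nodal_names)) {
      rk <- identify_hubs(rank_nodes(nodal_values[[m]][[cond]]),
                          fraction = config$hub_fraction)
      hubs[[cond]][[m]] <- rk
      hub_flags[cond, m] <- rk$hub[truth$target_node]
      target_ranks[cond, m] <- rk$rank[truth$target_node]
      comparisons[[cond]][[m]] <- target_vs_nodes_permutation(
        nodal_values[[m]][[cond]], target = truth$target_node,
        n_perm = config$n_perm,
        seed = salt_seed(config$seed, paste0("nodewise:", cond, ":", m))
      )
    }
  }
  roles <- classify_roles(hub_flags)

  ## --- condition statistics -----------------------------------------------
  stats_out <- lapply(global_measures, function(m) {
    res <- rm_permutation_test(global_table[[m]], n_perm = config$n_perm,
                               seed = salt_seed(config$seed, paste0("rm:", m)))
    c(list(measure = m, conditions = conditions), res)
  })
  names(stats_out) <- global_measures
  # target participation across task conditions + post-hoc pairs
  p_target <- sapply(task_conditions, function(cond) {
    nodal_values[["P"]][[cond]][, truth$target_node]
  })
  stats_out$target_participation <- c(
    list(measure = "target_P", conditions = task_conditions),
    rm_permutation_test(p_target, n_perm = config$n_perm,
                        seed = salt_seed(config$seed, "rm:target_P"))
  )
  pairs <- utils::combn(task_conditions, 2, simplify = FALSE)
  posthoc <- do.call(rbind, lapply(pairs, function(pr) {
    res <- pairwise_permutation(p_target[, pr[1]], p_target[, pr[2]],
                                n_perm = config$n_perm,
                                seed = salt_seed(config$seed,
                                                 paste0("pair:", pr[1], pr[2])))
    data.frame(cond1 = pr[1], cond2 = pr[2], statistic = res$statistic,
               p = res$p, stringsAsFactors = FALSE)
  }))
  posthoc$p_fdr <- fdr_correct(posthoc$p)

  ## --- behavior ------------------------------------------------------------
  behavior <- do.call(rbind, lapply(task_conditions, function(cond) {
    rt <- cohort$behavior$rt[cohort$behavior$condition == cond]
    res <- behavior_correlation(p_target[, cond], rt)
    data.frame(condition = cond, r = res$r, p = res$p, n = res$n,
               stringsAsFactors = FALSE)
  }))

  report <- list(
    density = density,
    primary_density = d_primary,
    partitions = partitions,
    group_partitions = group,
    subnetworks = subnetworks,
    metrics = metrics,
    global_table = global_table,
    hubs = hubs,
    target_ranks = target_ranks,
    roles = roles,
    comparisons = comparisons,
    stats = stats_out,
    posthoc = posthoc,
    behavior = behavior,
    manifest = list(
      package = "betanet",
      version = as.character(utils::packageVersion("betanet")),
      seed = config$seed,
      n_participants = length(participants),
      n_nodes = n,
      conditions = conditions,
      densities = config$densities,
      primary_density = d_primary,
      gamma = config$gamma, n_louvain = config$n_louvain, tau = config$tau,
      hub_fraction = config$hub_fraction, n_perm = config$n_perm
    )
  )

  if (!is.null(config$out_dir)) {
    write_report(report, cohort, config$out_dir)
  }
  report
}

# Writes the report bundle's artifacts as delimited text / JSON.
write_report <- function(report, cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- cohort$truth
  for (p in names(report$partitions)) {
    for (cond in truth$conditions) {
      tag <- sprintf("%s_%s", p, cond)
      write_partition(report$partitions[[p]][[cond]], cohort$node_ids,
                      file.path(dir, sprintf("partition_%s.tsv", tag)))
      write.table(report$metrics[[p]][[cond]],
                  file.path(dir, sprintf("metrics_%s.tsv", tag)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  for (cond in truth$conditions) {
    write_partition(report$group_partitions[[cond]], cohort$node_ids,
                    file.path(dir, sprintf("group_partition_%s.tsv", cond)))
  }
  jsonlite::write_json(
    list(
      density = report$density,
      target_ranks = as.data.frame(report$target_ranks),
      roles = report$roles$matrix,
      subnetwork_of_target = lapply(report$subnetworks, `[[`, "target_label"),
      stats = lapply(report$stats, function(s) s[c("measure", "statistic",
                                                   "p", "n_perm", "seed")]),
      posthoc = report$posthoc,
      behavior = report$behavior,
      manifest = report$manifest
    ),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
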