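test_that("modularity matches closed forms and the brute-force formula", {
  a <- two_cliques(4)
  expect_equal(modularity_q(a, rep(1:2, each = 4)), 0.5)
  expect_equal(modularity_q(a, rep(1, 8)), 0)
  # random memberships against the direct double-sum, including gamma != 1
  set.seed(5)
  for (i in 1:20) {
    g <- random_graph(sample(4:7, 1), 0.5)
    if (sum(g) == 0) next
    mem <- sample(1:3, nrow(g), replace = TRUE)
    gamma <- sample(c(0.5, 1, 1.3), 1)
    expect_equal(modularity_q(g, mem, gamma),
                 brute_modularity(g, mem, gamma), tolerance = 1e-12)
  }
  # any partition of a complete graph scores <= 0 (brute force over K4)
  k4 <- graph_complete(4)
  qs <- vapply(all_partitions(4), function(p) brute_modularity(k4, p),
               numeric(1))
  expect_true(all(qs <= 1e-12))
  for (p in all_partitions(4)[c(2, 7, 14)]) {
    expect_lte(modularity_q(k4, p), 1e-12)
  }
  expect_error(modularity_q(matrix(0, 3, 3), c(1, 1, 2)), "edgeless")
})

test_that("Louvain recovers optimal partitions on tiny graphs", {
  a <- two_cliques(3)
  # exhaustive oracle: the best partition over all set partitions of 6 nodes
  qs <- vapply(all_partitions(6), function(p) brute_modularity(a, p),
               numeric(1))
  best <- max(qs)
  lp <- louvain_partition(a, seed = 2)
  expect_equal(lp$q, best, tolerance = 1e-12)
  expect_equal(lp$q, 0.5)
  expect_equal(lp$membership, rep(1:2, each = 3))
  # returned q always equals modularity recomputed from the assignment
  expect_equal(lp$q, modularity_q(a, lp$membership))
  # complete graph collapses to one community
  expect_equal(louvain_partition(graph_complete(5), seed = 1)$n_communities, 1)
  # q at least as good as the all-singleton start
  set.seed(9)
  g <- random_graph(10, 0.3)
  if (sum(g) > 0) {
    lp <- louvain_partition(g, seed = 3)
    expect_gte(lp$q, modularity_q(g, 1:10))
    expect_equal(lp$q, modularity_q(g, lp$membership), tolerance = 1e-12)
  }
})

test_that("consensus partitioning converges to the dominant structure", {
  a <- two_cliques(3)
  ref <- rep(1:2, each = 3)
  # identical inputs return immediately
  out <- consensus_partition(list(ref, ref, ref), n_runs = 20, seed = 1)
  expect_equal(out$membership, ref)
  expect_equal(attr(out, "n_iter"), 0L)
  # 90 copies of the true structure plus 10 noise partitions
  set.seed(3)
  noise <- replicate(10, sample(1:3, 6, replace = TRUE), simplify = FALSE)
  parts <- c(replicate(90, ref, simplify = FALSE), noise)
  out <- consensus_partition(parts, n_runs = 20, seed = 4, graph = a)
  expect_equal(out$membership, ref)
  expect_equal(out$q, 0.5)
  # mutually inconsistent partitions with no super-threshold agreement
  p1 <- c(1, 1, 2, 2, 3, 3)
  p2 <- c(1, 2, 1, 3, 2, 3)
  p3 <- c(3, 1, 1, 2, 3, 2)
  expect_warning(
    out <- consensus_partition(list(p1, p2, p3), tau = 0.9, n_runs = 10,
                               seed = 1),
    "singleton"
  )
  expect_equal(out$n_communities, 6)
})

test_that("consensus is idempotent", {
  set.seed(6)
  ref <- rep(1:2, each = 3)
  noise <- replicate(5, sample(1:2, 6, replace = TRUE), simplify = FALSE)
  out <- consensus_partition(c(replicate(20, ref, simplify = FALSE), noise),
                             n_runs = 20, seed = 2)
  again <- consensus_partition(list(out, out), n_runs = 20, seed = 3)
  expect_equal(again$membership, out$membership)
})

test_that("group representative reduces shared structure to one partition", {
  ref <- rep(1:2, each = 4)
  gp <- group_representative(replicate(6, ref, simplify = FALSE),
                             n_runs = 10, seed = 1)
  expect_equal(gp$membership, ref)
  expect_equal(gp$level, "group")
  # participants with disjoint structure are flagged (and the downstream
  # consensus degenerates to singletons)
  expect_warning(
    expect_warning(
      group_representative(list(c(1, 1, 2, 2), c(1, 2, 1, 2)),
                           tau = 0.6, n_runs = 10, seed = 1),
      "degenerate"
    ),
    "singleton"
  )
})

test_that("NMI follows the contingency-table definition and conventions", {
  p <- c(1, 1, 2, 2, 3, 3)
  relabeled <- c(3, 3, 1, 1, 2, 2)
  expect_equal(nmi(p, relabeled), 1)
  expect_equal(nmi(p, rep(1, 6)), 0)
  # crossing pairs on 4 nodes: uniform contingency table, zero information
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)
  # symmetry and relabel-invariance on random partitions; igraph as the
  # independent cross-check
  set.seed(12)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:4, n, replace = TRUE)
    expect_equal(nmi(a, b), nmi(b, a), tolerance = 1e-12)
    expect_equal(nmi(a, b), igraph::compare(a, b, method = "nmi"),
                 tolerance = 1e-12)
  }
  expect_equal(nmi(rep(1, 5), rep(2, 5)), 1)  # identical up to relabeling
})

test_that("sub-network labeling assigns maximal-Jaccard reference labels", {
  ref <- rep(c("VN", "FPN"), each = 5)
  # identical partition -> identity map with Jaccard 1
  out <- label_subnetworks(rep(1:2, each = 5), ref)
  expect_equal(unname(out$labels), c("VN", "FPN"))
  expect_equal(out$overlap$jaccard[out$overlap$community == 1 &
                                   out$overlap$label == "VN"], 1)
  # a community straddling two reference networks 60/40
  mem <- c(rep(1, 5), rep(1, 3), 2, 2)  # community 1: 5 VN + 3 FPN nodes
  out <- label_subnetworks(mem, ref)
  expect_equal(unname(out$labels[1]), "VN")
  both <- out$overlap[out$overlap$community == 1, ]
  expect_equal(both$intersection[both$label == "VN"], 5)
  expect_equal(both$intersection[both$label == "FPN"], 3)
  # unlabeled nodes forming their own community come out unassigned
  ref_na <- c(rep("VN", 8), NA, NA)
  out <- label_subnetworks(c(rep(1, 8), 2, 2), ref_na)
  expect_equal(unname(out$labels[2]), "unassigned")
  expect_error(label_subnetworks(rep(1, 10), c(rep("VN", 5), rep(NA, 5))),
               "cover")
  # target node's community label is reported
  out <- label_subnetworks(rep(1:2, each = 5), ref, target_node = 7)
  expect_equal(out$target_label, "FPN")
})

test_that("planted community structure and target switching are recovered", {
  # at this small scale only the strongly concentrated layouts (baseline in
  # FPN, CN+ in VN) give the target an unambiguous community; the connector
  # layouts are exercised at full scale in the recovery suite
  tr <- tiny_truth(seed = 5, n_participants = 3, n_trials = 80)
  reference <- tr$module_labels[tr$partition]
  labels <- character(0)
  for (cond in c("baseline", "CN+")) {
    parts <- lapply(seq_len(3), function(p) {
      set.seed(betanet:::salt_seed(tr$seed, paste0("beta:", cond), p))
      r <- build_block_correlation(tr, cond)
      e <- eigen(r, symmetric = TRUE)
      b <- matrix(rnorm(tr$n_trials * tr$n_nodes), tr$n_trials) %*%
        t(e$vectors %*% diag(sqrt(pmax(e$values, 0))))
      a <- proportional_threshold(beta_correlation(b), 20)
      network_consensus(a, n_runs = 30, seed = p)
    })
    gp <- group_representative(parts, n_runs = 30, seed = 7)
    expect_gte(nmi(gp, tr$partition), 0.8)
    labels[cond] <- label_subnetworks(gp, reference,
                                      target_node = tr$target_node)$target_label
  }
  # the planted role profile moves the target across sub-networks
  expect_equal(unname(labels["baseline"]), "FPN")
  expect_equal(unname(labels["CN+"]), "VN")
})
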