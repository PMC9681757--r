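test_that("ground truth validates its invariants", {
  expect_s3_class(tiny_truth(), "betanet_truth")
  expect_error(ground_truth(n_nodes = 10, module_sizes = c(5, 5, 5)),
               "sum to")
  expect_error(ground_truth(n_nodes = 8, module_sizes = c(2, 3, 3),
                            role_profile = diag(3)[c(1, 1, 1, 2, 3), ]),
               ">= 3")
  expect_error(tiny_truth_bad <- ground_truth(rho_in = 0.3, rho_out = 0.3),
               "rho_out < rho_in")
  bad_profile <- matrix(0.3, 5, 4,
                        dimnames = list(c("baseline", "PN-", "PN+", "CN-", "CN+"),
                                        NULL))
  expect_error(ground_truth(role_profile = bad_profile), "sum to 1")
  tr <- tiny_truth()
  expect_equal(sort(unique(tr$partition)), 1:4)
  expect_true(all(tabulate(tr$partition) >= 3))
  expect_equal(unname(rowSums(tr$role_profile)), rep(1, 5))
})

test_that("block correlation matrix matches direct construction", {
  # two modules of three nodes; the target's profile keeps it an ordinary
  # member of module 1, so the matrix is the pure block pattern
  profile <- matrix(rep(c(1, 0), each = 5), 5, 2,
                    dimnames = list(c("baseline", "PN-", "PN+", "CN-", "CN+"),
                                    c("A", "B")))
  tr <- ground_truth(n_nodes = 6, module_sizes = c(3, 3),
                     module_labels = c("A", "B"), role_profile = profile,
                     rho_in = 0.5, rho_out = 0.1,
                     n_participants = 3, seed = 1)
  r <- build_block_correlation(tr, "baseline")
  expected <- matrix(0.1, 6, 6)
  expected[1:3, 1:3] <- 0.5
  expected[4:6, 4:6] <- 0.5
  diag(expected) <- 1
  expect_equal(r, expected, tolerance = 1e-12)
})

test_that("default 263-node layout is positive semidefinite", {
  tr <- ground_truth(seed = 1)
  # the plain block structure (target an ordinary module member) needs no
  # repair: all eigenvalues non-negative and entries exactly at the two levels
  profile <- matrix(rep(c(1, 0, 0, 0), each = 5), 5, 4,
                    dimnames = list(tr$conditions, tr$module_labels))
  tr0 <- ground_truth(role_profile = profile, seed = 1)
  r0 <- build_block_correlation(tr0, "baseline")
  ev0 <- eigen(r0, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev0), -1e-8)
  off <- r0[upper.tri(r0)]
  expect_true(all(abs(off - tr$rho_in) < 1e-9 | abs(off - tr$rho_out) < 1e-9))
  # the condition-specific target override can make the raw matrix
  # indefinite; the returned matrix is always a repaired valid correlation
  for (cond in c("baseline", "PN-", "CN+")) {
    r <- build_block_correlation(tr, cond)
    ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
    expect_equal(diag(r), rep(1, 263))
    expect_equal(r, t(r))
  }
})

test_that("target row follows the condition's role profile", {
  tr <- ground_truth(seed = 1)
  tn <- tr$target_node
  budget <- tr$module_sizes[tr$partition[tn]] - 1
  # connector layout: the strongest entries of the target row spread over all
  # modules in the profile's proportions (repair attenuates magnitudes but
  # preserves the planted contrast)
  r <- build_block_correlation(tr, "PN-")
  row <- r[tn, -tn]
  strong <- order(row, decreasing = TRUE)[seq_len(budget)]
  counts <- table(factor(tr$partition[-tn][strong], levels = 1:4))
  expect_equal(unname(round(as.vector(counts) / budget, 1)),
               unname(round(tr$role_profile["PN-", ], 1)))
  expect_gt(min(row[strong]), max(row[-strong]))  # clear strong/weak gap
  # concentrated layout: strong entries pile into the visual-like module
  r2 <- build_block_correlation(tr, "CN+")
  row2 <- r2[tn, -tn]
  strong2 <- order(row2, decreasing = TRUE)[seq_len(budget)]
  expect_gte(mean(tr$partition[-tn][strong2] == 1), 0.69)
})

test_that("eigenvalue clipping repairs an indefinite matrix", {
  r <- matrix(0.9, 3, 3)
  r[1, 2] <- r[2, 1] <- -0.9  # indefinite: strong contradiction
  diag(r) <- 1
  expect_lt(min(eigen(r, symmetric = TRUE, only.values = TRUE)$values), 0)
  r2 <- betanet:::repair_psd(r)
  expect_gte(min(eigen(r2, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  expect_equal(diag(r2), rep(1, 3))
  expect_equal(r2, t(r2))
})

test_that("sampled correlations converge to the planted pattern", {
  profile <- matrix(rep(c(1, 0), each = 5), 5, 2,
                    dimnames = list(c("baseline", "PN-", "PN+", "CN-", "CN+"),
                                    c("A", "B")))
  tr <- ground_truth(n_nodes = 6, module_sizes = c(3, 3),
                     module_labels = c("A", "B"), role_profile = profile,
                     rho_in = 0.5, rho_out = 0.1,
                     behavior_r = c("PN-" = 0, "PN+" = 0, "CN-" = 0, "CN+" = 0),
                     n_trials = 4000, n_participants = 3, seed = 7)
  co <- sample_cohort(tr, density = 50)
  b <- co$beta[[1]][["baseline"]]
  r <- cor(b)
  expect_lt(abs(r[1, 2] - 0.5), 0.05)  # same module
  expect_lt(abs(r[1, 4] - 0.1), 0.05)  # different modules
})

test_that("cohort sampling is seed-reproducible and participant-independent", {
  tr <- tiny_truth(seed = 3)
  c1 <- sample_cohort(tr)
  c2 <- sample_cohort(tr)
  expect_identical(c1$beta, c2$beta)
  expect_identical(c1$behavior, c2$behavior)
  expect_false(identical(c1$beta[[1]][["baseline"]],
                         c1$beta[[2]][["baseline"]]))
  # different master seed changes the draws
  c3 <- sample_cohort(tiny_truth(seed = 4))
  expect_false(identical(c1$beta[[1]][["baseline"]],
                         c3$beta[[1]][["baseline"]]))
  # structure invariants
  expect_equal(length(c1$beta), tr$n_participants)
  for (p in seq_along(c1$beta)) {
    for (cond in tr$conditions) {
      expect_equal(dim(c1$beta[[p]][[cond]]), c(tr$n_trials, tr$n_nodes))
      expect_false(anyNA(c1$beta[[p]][[cond]]))
    }
  }
})

test_that("planted behavior has the requested correlation structure", {
  particip <- rnorm(24)
  # perfect negative correlation leaves no noise
  rt <- generate_behavior(particip, r_target = -1, seed = 5)
  expect_equal(cor(particip, rt), -1, tolerance = 1e-12)
  # r = 0 gives sample correlations scattered around zero
  rs <- vapply(1:200, function(s) {
    cor(particip, generate_behavior(particip, 0, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)
  expect_error(generate_behavior(rep(1, 10), r_target = -0.5), "zero variance")
  expect_error(generate_behavior(c(1, 2), r_target = 0), "at least 3")
})

test_that("reference ROI bookkeeping yields the analysis node set", {
  ref <- make_reference_nodes()
  expect_equal(nrow(ref), 264)
  expect_equal(sum(!ref$gray_matter), 1)
  roi <- assemble_roi_set(ref)
  expect_equal(nrow(roi), 263)
  expect_equal(roi$node_id[attr(roi, "target_node")], "target")
  # the overlapping reference ROI is gone, the non-gray one too
  expect_false("ref264" %in% roi$node_id)
  expect_false(ref$node_id[!ref$gray_matter] %in% roi$node_id)
})
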