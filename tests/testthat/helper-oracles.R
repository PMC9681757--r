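# Brute-force oracles for graph measures, independent of both the package
# implementation and igraph: everything is derived from exhaustive simple-path
# enumeration or direct definition loops. Intended for graphs with <= 7 nodes.

# All shortest paths between s and t as a list of node sequences.
brute_shortest_paths_st <- function(a, s, t) {
  best <- Inf
  acc <- list()
  rec <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      len <- length(path) - 1L
      if (len < best) {
        best <<- len
        acc <<- list(path)
      } else if (len == best) {
        acc[[length(acc) + 1L]] <<- path
      }
      return(invisible())
    }
    if (length(path) - 1L >= best) return(invisible())
    for (u in which(a[v, ] > 0)) {
      if (!(u %in% path)) rec(c(path, u))
    }
  }
  rec(s)
  list(dist = if (length(acc)) best else Inf, paths = acc)
}

# Distances, shortest-path counts, and betweenness from path enumeration.
brute_path_census <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n); diag(d) <- 0
  sigma <- matrix(0, n, n); diag(sigma) <- 1
  btw <- numeric(n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t) next
      sp <- brute_shortest_paths_st(a, s, t)
      d[s, t] <- sp$dist
      sigma[s, t] <- length(sp$paths)
      if (s < t && length(sp$paths)) {
        interior <- unlist(lapply(sp$paths, function(p) p[-c(1, length(p))]))
        for (v in interior) btw[v] <- btw[v] + 1 / length(sp$paths)
      }
    }
  }
  list(dist = d, sigma = sigma, betweenness = btw)
}

brute_global_efficiency <- function(a) {
  n <- nrow(a)
  d <- brute_path_census(a)$dist
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

brute_clustering <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    t_i <- 0
    for (u in nb) for (v in nb) if (u < v && a[u, v] > 0) t_i <- t_i + 1
    2 * t_i / (k * (k - 1))
  }, numeric(1))
}

brute_flow <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    open <- 0; total <- 0
    for (u in nb) for (v in nb) if (u < v) {
      total <- total + 1
      if (a[u, v] == 0) open <- open + 1
    }
    open / total
  }, numeric(1))
}

brute_participation <- function(a, membership) {
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    k <- sum(a[i, ])
    if (k == 0) return(0)
    1 - sum(vapply(unique(membership), function(m) {
      (sum(a[i, membership == m]) / k)^2
    }, numeric(1)))
  }, numeric(1))
}

brute_modularity <- function(a, membership, gamma = 1) {
  two_m <- sum(a)
  k <- rowSums(a)
  q <- 0
  n <- nrow(a)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (membership[i] == membership[j]) {
      q <- q + a[i, j] - gamma * k[i] * k[j] / two_m
    }
  }
  q / two_m
}

# All set partitions of 1..n (restricted-growth enumeration); for exhaustive
# modularity maximization on tiny graphs.
all_partitions <- function(n) {
  out <- list()
  rec <- function(assign, next_id) {
    i <- length(assign) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- assign
      return(invisible())
    }
    for (c in seq_len(next_id)) {
      rec(c(assign, c), max(next_id, c + 1L))
    }
  }
  rec(integer(0), 1L)
  out
}

# Random connected-ish undirected graph on n nodes (not necessarily connected;
# metrics must handle both).
random_graph <- function(n, p = 0.4) {
  a <- matrix(0L, n, n)
  ut <- upper.tri(a)
  a[ut] <- as.integer(runif(sum(ut)) < p)
  a + t(a)
}

# Small deterministic graphs used across tests
graph_path3 <- function() {
  a <- matrix(0L, 3, 3); a[1, 2] <- a[2, 3] <- 1L; a + t(a)
}
graph_star <- function(n_leaves) {
  a <- matrix(0L, n_leaves + 1, n_leaves + 1)
  a[1, 2:(n_leaves + 1)] <- 1L
  a + t(a)
}
graph_complete <- function(n) {
  a <- matrix(1L, n, n); diag(a) <- 0L; a
}
graph_cycle <- function(n) {
  a <- matrix(0L, n, n)
  for (i in seq_len(n)) a[i, i %% n + 1] <- 1L
  a + t(a)
}
two_cliques <- function(k) {
  a <- matrix(0L, 2 * k, 2 * k)
  a[1:k, 1:k] <- 1L
  a[(k + 1):(2 * k), (k + 1):(2 * k)] <- 1L
  diag(a) <- 0L
  a
}

# Tiny ground truth reused in several suites
tiny_truth <- function(seed = 1, n_participants = 4, n_trials = 60) {
  ground_truth(
    n_nodes = 40, module_sizes = c(10, 10, 10, 10),
    module_labels = c("VN", "FPN", "DMN", "SAN"),
    n_participants = n_participants, n_trials = n_trials, seed = seed
  )
}
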