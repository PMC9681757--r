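#' Repeated-measures permutation test across conditions
#'
#' Omnibus test of any condition effect on a scalar measure observed for every
#' participant under every condition. The statistic is the between-condition
#' sum of squares of the condition means after within-participant centering;
#' the null distribution is built by independently permuting the condition
#' labels within each participant (the exchangeability the repeated-measures
#' design affords). The p-value uses the add-one convention
#' `p = (1 + #{perm >= obs}) / (1 + n_perm)` and so never reports 0.
#'
#' @param tab participants x conditions numeric matrix (complete; no missing
#'   cells).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return list with `statistic`, `p`, `n_perm`, `seed`.
#' @export
rm_permutation_test <- function(tab, n_perm = 10000, seed = 1L) {
  tab <- as.matrix(tab)
  n <- nrow(tab); k <- ncol(tab)
  if (k < 2) stop("need at least 2 conditions", call. = FALSE)
  if (n < 2) stop("need at least 2 participants", call. = FALSE)
  if (anyNA(tab)) stop("condition table must be complete", call. = FALSE)
  centered <- tab - rowMeans(tab)
  obs <- sum(colMeans(centered)^2)
  if (all(abs(centered) < 1e-14)) {
    warning("constant condition table; the test has no resolution")
    return(list(statistic = 0, p = 1, n_perm = n_perm, seed = seed))
  }
  set.seed(salt_seed(seed, "rm-permutation"))
  eps <- 1e-12
  count <- 0L
  perm_row <- matrix(0, n, k)
  for (b in seq_len(n_perm)) {
    for (i in seq_len(n)) perm_row[i, ] <- centered[i, sample.int(k)]
    if (sum(colMeans(perm_row)^2) >= obs - eps) count <- count + 1L
  }
  list(statistic = obs, p = (1 + count) / (1 + n_perm),
       n_perm = n_perm, seed = seed)
}

#' Pairwise (post-hoc) permutation test between two conditions
#'
#' Paired sign-flip permutation test on within-participant differences. The
#' statistic is the absolute mean difference (two-sided). All `2^n` sign
#' patterns are enumerated when that is no more than `n_perm`; otherwise
#' `n_perm` Monte-Carlo draws are used with the add-one p-value convention.
#'
#' @param x,y paired numeric vectors (one value per participant under each of
#'   the two conditions); alternatively `x` may be a 2-column matrix and `y`
#'   NULL.
#' @param n_perm permutation budget (default 10000).
#' @param seed integer seed for the Monte-Carlo mode.
#' @param exact force exhaustive (`TRUE`) or Monte-Carlo (`FALSE`)
#'   enumeration; `NULL` (default) picks exhaustive whenever `2^n <= n_perm`.
#' @return list with `statistic` (mean difference, signed), `p` (two-sided),
#'   `exhaustive`, `n_perm`, `seed`.
#' @export
pairwise_permutation <- function(x, y = NULL, n_perm = 10000, seed = 1L,
                                 exact = NULL) {
  if (is.null(y)) {
    x <- as.matrix(x)
    if (ncol(x) != 2) stop("`x` must have 2 columns when `y` is NULL",
                           call. = FALSE)
    y <- x[, 2]; x <- x[, 1]
  }
  if (length(x) != length(y)) stop("`x` and `y` must be paired", call. = FALSE)
  d <- x - y
  n <- length(d)
  obs <- mean(d)
  if (all(abs(d) < 1e-14)) {
    warning("identical conditions; the test has no resolution")
    return(list(statistic = 0, p = 1, exhaustive = TRUE,
                n_perm = n_perm, seed = seed))
  }
  eps <- 1e-12
  exhaustive <- if (is.null(exact)) 2^n <= n_perm else isTRUE(exact)
  if (exhaustive) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    perm <- abs(signs %*% d) / n
    p <- mean(perm >= abs(obs) - eps)
  } else {
    set.seed(salt_seed(seed, "pairwise-permutation"))
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    perm <- abs(signs %*% d) / n
    p <- (1 + sum(perm >= abs(obs) - eps)) / (1 + n_perm)
  }
  list(statistic = obs, p = p, exhaustive = exhaustive,
       n_perm = n_perm, seed = seed)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up FDR adjustment of a vector of p-values, used to confirm results
#' across the analysis density range rather than at a single density.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values (monotone, never below the raw values).
#' @export
fdr_correct <- function(p) {
  if (!length(p)) stop("no p-values supplied", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Brain-behavior correlation
#'
#' Pearson correlation between a nodal measure (one value per participant,
#' e.g. the target node's participation coefficient) and a behavioral score
#' (e.g. reaction time), with the two-sided t-based p-value.
#'
#' @param x,y numeric vectors of per-participant values (`n >= 4`, finite,
#'   non-constant).
#' @return list with `r`, `p`, `n`.
#' @export
behavior_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must be paired", call. = FALSE)
  if (length(x) < 4) stop("need at least 4 participants", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite values", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance; correlation undefined", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
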