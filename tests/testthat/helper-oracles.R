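# Independent oracles, deliberately coded with naive loops and base-R
# primitives that do not share code paths with the package internals.

# Bayes-rule posterior for a Gaussian equal-covariance classifier, via
# stats::mahalanobis (not the package's Cholesky machinery).
oracle_gaussian_posterior <- function(X, means, sigma, prior) {
  q <- sapply(seq_len(nrow(means)), function(k)
    prior[k] * exp(-0.5 * stats::mahalanobis(X, means[k, ], sigma)))
  q <- matrix(q, nrow = nrow(X))
  q / rowSums(q)
}

oracle_node_deviance <- function(y, K) {
  n <- length(y)
  d <- 0
  for (k in seq_len(K)) {
    ck <- sum(y == k)
    if (ck > 0) d <- d - 2 * ck * log(ck / n)
  }
  d
}

# Exhaustive-split deviance tree grown with plain loops: at each node every
# (predictor, cut) pair is scored directly; both children must have at
# least min_node rows and the deviance reduction must reach
# frac * root deviance. Ties: lowest predictor, then lowest cut.
oracle_tree <- function(X, y, K, min_node = 10, frac = 0.01) {
  root_dev <- oracle_node_deviance(y, K)
  grow <- function(X, y) {
    n <- length(y)
    node <- list(prob = sapply(seq_len(K), function(k) mean(y == k)),
                 leaf = TRUE)
    dev <- oracle_node_deviance(y, K)
    if (n < 2 * min_node || dev <= 0) return(node)
    best <- NULL
    for (j in seq_len(ncol(X))) {
      xs <- sort(unique(X[, j]))
      if (length(xs) < 2) next
      for (c_i in seq_len(length(xs) - 1)) {
        cut <- (xs[c_i] + xs[c_i + 1]) / 2
        left <- X[, j] < cut
        if (sum(left) < min_node || sum(!left) < min_node) next
        d <- oracle_node_deviance(y[left], K) +
          oracle_node_deviance(y[!left], K)
        if (is.null(best) || d < best$d - 1e-12)
          best <- list(j = j, cut = cut, d = d)
      }
    }
    if (is.null(best) || dev - best$d < frac * root_dev) return(node)
    left <- X[, best$j] < best$cut
    list(leaf = FALSE, var = best$j, cut = best$cut,
         l = grow(X[left, , drop = FALSE], y[left]),
         r = grow(X[!left, , drop = FALSE], y[!left]))
  }
  grow(X, y)
}

oracle_tree_posterior <- function(tree, X) {
  one <- function(node, x) {
    while (!node$leaf) node <- if (x[node$var] < node$cut) node$l else node$r
    node$prob
  }
  t(apply(X, 1, function(x) one(tree, x)))
}

# Random small classification fixtures with continuous predictors.
random_fixture <- function(n, K = 2, p = 2, shift = 1.5) {
  y <- sample(seq_len(K), n, replace = TRUE)
  while (length(unique(y)) < K) y <- sample(seq_len(K), n, replace = TRUE)
  X <- matrix(stats::rnorm(n * p), n, p) + shift * y
  colnames(X) <- paste0("x", seq_len(p))
  list(X = X, group = y)
}
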