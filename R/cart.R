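#' Classification tree with deviance splitting
#'
#' Greedy binary recursive partitioning. The node impurity is the
#' multinomial deviance `D = -2 * sum_k n_k * log(n_k / n)` (with
#' `0 * log 0 = 0`). At each node every axis-aligned cut on every predictor
#' is scored, and the best split is accepted only if (a) both children would
#' contain at least `min_node_size` observations (default 10) and (b) the
#' deviance reduction is at least `min_deviance_fraction` (default 0.01) of
#' the *root* deviance. Leaves predict their majority class; the leaf class
#' proportions are the posterior probabilities. Ties among equally good
#' splits go to the lowest predictor index, then the lowest cut point.
#'
#' @inheritParams fit_lda
#' @param config A [method_config()]; `config$cart` holds
#'   `min_deviance_fraction` and `min_node_size`.
#' @return A fitted classifier; `$nodes` is the node table (a list), `$n_leaves`
#'   the number of terminal nodes.
#' @export
fit_cart <- function(train, config = method_config()) {
  tr <- as_training(train)
  n <- nrow(tr$X); K <- tr$K
  min_node <- config$cart$min_node_size
  if (n < min_node)
    stop("training sample smaller than the minimum node size", call. = FALSE)
  root_dev <- node_deviance(tabulate(tr$y, K))
  threshold <- config$cart$min_deviance_fraction * root_dev
  env <- new.env()
  env$nodes <- list()
  grow <- function(rows) {
    yk <- tabulate(tr$y[rows], K)
    nn <- length(rows)
    dev <- node_deviance(yk)
    node <- list(leaf = TRUE, n = nn, prob = yk / nn, deviance = dev,
                 var = NA_integer_, cut = NA_real_,
                 left = NA_integer_, right = NA_integer_)
    id <- length(env$nodes) + 1L
    env$nodes[[id]] <- node
    if (nn >= 2 * min_node && dev > 0) {
      sp <- best_deviance_split(tr$X[rows, , drop = FALSE], tr$y[rows],
                                K, min_node)
      if (!is.null(sp) && dev - sp$children_deviance >= threshold) {
        go_left <- tr$X[rows, sp$var] < sp$cut
        left <- grow(rows[go_left])
        right <- grow(rows[!go_left])
        node$leaf <- FALSE
        node$var <- sp$var; node$cut <- sp$cut
        node$left <- left; node$right <- right
        env$nodes[[id]] <- node
      }
    }
    id
  }
  grow(seq_len(n))
  if (length(env$nodes) == 1L)
    message("no admissible split at the root; returning a single-leaf ",
            "(majority class) tree")
  new_classifier("cart",
                 list(nodes = env$nodes, root = 1L,
                      n_leaves = sum(vapply(env$nodes, `[[`, TRUE, "leaf")),
                      root_deviance = root_dev),
                 n_classes = K, p = ncol(tr$X))
}

# 0 log 0 := 0
xlogx <- function(v) ifelse(v > 0, v * log(v), 0)

# Multinomial node deviance from class counts.
node_deviance <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  -2 * sum(xlogx(counts)) + 2 * n * log(n)
}

# Best admissible cut over all predictors: minimizes the summed deviance of
# the two children subject to both children having >= min_node rows. Returns
# NULL when no cut is admissible. Deterministic tie-break: lowest predictor,
# then lowest cut.
best_deviance_split <- function(X, y, K, min_node) {
  n <- length(y)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    o <- order(X[, j])
    xo <- X[o, j]
    cum <- vapply(seq_len(K), function(k) cumsum(y[o] == k),
                  numeric(n))
    i <- seq_len(n - 1)
    ok <- i >= min_node & (n - i) >= min_node & xo[i] < xo[i + 1]
    if (!any(ok)) next
    i <- i[ok]
    left_counts <- cum[i, , drop = FALSE]
    tot <- cum[n, ]
    right_counts <- rep(tot, each = length(i)) - left_counts
    devL <- 2 * (i * log(i) - rowSums(xlogx(left_counts)))
    devR <- 2 * ((n - i) * log(n - i) - rowSums(xlogx(right_counts)))
    d <- devL + devR
    b <- which.min(d)
    if (is.null(best) || d[b] < best$children_deviance - 1e-12) {
      best <- list(var = j, cut = (xo[i[b]] + xo[i[b] + 1]) / 2,
                   children_deviance = d[b])
    }
  }
  best
}

#' @export
posterior_matrix.cart_model <- function(object, X) {
  n <- nrow(X)
  post <- matrix(0, n, object$n_classes)
  descend <- function(id, rows) {
    node <- object$nodes[[id]]
    if (node$leaf) {
      post[rows, ] <<- matrix(node$prob, length(rows), object$n_classes,
                              byrow = TRUE)
      return(invisible(NULL))
    }
    go_left <- X[rows, node$var] < node$cut
    if (any(go_left)) descend(node$left, rows[go_left])
    if (any(!go_left)) descend(node$right, rows[!go_left])
  }
  descend(object$root, seq_len(n))
  post
}
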