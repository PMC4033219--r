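#' Multinomial logistic regression
#'
#' Baseline-category multinomial logit fitted by Newton-Raphson on the
#' multinomial log-likelihood (with step halving). The last class is the
#' baseline; with two classes this is ordinary binary logistic regression.
#' Under complete or quasi-separation the likelihood has no finite maximum:
#' fitting stops at the iteration cap with a warning and returns the current
#' (saturating) model, which still predicts.
#'
#' @inheritParams fit_lda
#' @param config A [method_config()]; `config$lr` holds the Newton
#'   convergence tolerance (on the mean score) and iteration cap.
#' @return A fitted classifier; `$coef` is the (p + 1) x (K - 1) coefficient
#'   matrix (intercept first).
#' @export
fit_multinomial_lr <- function(train, config = method_config()) {
  tr <- as_training(train)
  n <- nrow(tr$X); K <- tr$K
  X1 <- cbind(1, tr$X)
  d <- ncol(X1)
  Y <- matrix(0, n, K - 1)
  for (j in seq_len(K - 1)) Y[, j] <- as.numeric(tr$y == j)
  B <- matrix(0, d, K - 1)
  ll <- lr_loglik(X1, tr$y, B, K)
  tol <- config$lr$tol
  converged <- FALSE
  for (it in seq_len(config$lr$max_iter)) {
    P <- softmax_rows(cbind(X1 %*% B, 0))[, seq_len(K - 1), drop = FALSE]
    G <- crossprod(X1, Y - P)                     # d x (K-1) score
    if (max(abs(G)) < tol * n) { converged <- TRUE; break }
    H <- matrix(0, d * (K - 1), d * (K - 1))
    for (j in seq_len(K - 1)) for (l in seq_len(j)) {
      w <- if (j == l) P[, j] * (1 - P[, j]) else -P[, j] * P[, l]
      blk <- crossprod(X1, X1 * w)
      rj <- (j - 1) * d + seq_len(d); rl <- (l - 1) * d + seq_len(d)
      H[rj, rl] <- blk
      if (j != l) H[rl, rj] <- blk
    }
    step <- tryCatch(solve(H, as.vector(G)), error = function(e)
      solve(H + 1e-8 * max(diag(H)) * diag(nrow(H)), as.vector(G)))
    step <- matrix(step, d, K - 1)
    # step halving: never accept a decrease in log-likelihood
    alpha <- 1
    repeat {
      Bnew <- B + alpha * step
      llnew <- lr_loglik(X1, tr$y, Bnew, K)
      if (llnew >= ll - 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    if (abs(llnew - ll) < tol * (abs(ll) + tol)) {
      B <- Bnew; ll <- llnew; converged <- TRUE; break
    }
    B <- Bnew; ll <- llnew
  }
  if (!converged)
    warning("multinomial logit did not converge in ", config$lr$max_iter,
            " iterations (possible separation); returning current fit",
            call. = FALSE)
  P_full <- softmax_rows(cbind(X1 %*% B, 0))
  if (any(P_full[cbind(seq_len(n), tr$y)] > 1 - 1e-8))
    warning("fitted probabilities numerically 0 or 1 (possible separation)",
            call. = FALSE)
  coef <- B
  rownames(coef) <- c("(Intercept)", colnames(tr$X))
  new_classifier("lr", list(coef = coef, loglik = ll,
                            converged = converged),
                 n_classes = K, p = ncol(tr$X))
}

lr_loglik <- function(X1, y, B, K) {
  eta <- cbind(X1 %*% B, 0)
  m <- apply(eta, 1, max)
  sum(eta[cbind(seq_along(y), y)] - m - log(rowSums(exp(eta - m))))
}

#' @export
posterior_matrix.lr_model <- function(object, X) {
  softmax_rows(cbind(cbind(1, X) %*% object$coef, 0))
}
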