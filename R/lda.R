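#' Linear discriminant analysis
#'
#' Gaussian classifier with per-class mean vectors and a single pooled
#' within-class covariance (maximum-likelihood scaling), equal across
#' classes. Posterior probabilities follow Bayes' rule,
#' `P(k | x) ~ prior_k * phi(x; mu_k, Sigma)`; by default the priors are the
#' class frequencies observed in the training data.
#'
#' @param train A [labeled_dataset()] (or list with `X` and `group`); every
#'   class must be present.
#' @param config A [method_config()]; `config$lda$prior` selects
#'   data-estimated (default) or uniform priors.
#' @return A fitted classifier; see [predict.subgroup_classifier()].
#' @export
#' @examples
#' pair <- simulate_pair(simulation_design(2, 100, delta = 0.8), seed = 1)
#' m <- fit_lda(pair$train)
#' mean(predict(m, pair$cv)$class != pair$cv$group)
fit_lda <- function(train, config = method_config()) {
  tr <- as_training(train)
  n <- nrow(tr$X); p <- ncol(tr$X); K <- tr$K
  means <- matrix(0, K, p)
  pooled <- matrix(0, p, p)
  nk <- tabulate(tr$y, K)
  for (k in seq_len(K)) {
    Xk <- tr$X[tr$y == k, , drop = FALSE]
    means[k, ] <- colMeans(Xk)
    pooled <- pooled + crossprod(sweep(Xk, 2, means[k, ]))
  }
  sigma <- pooled / n
  prior <- if (config$lda$prior == "uniform") rep(1 / K, K) else nk / n
  ch <- safe_chol(sigma)
  new_classifier("lda", list(means = means, sigma = ch$sigma,
                             chol = ch$u, prior = prior),
                 n_classes = K, p = p)
}

#' @export
posterior_matrix.lda_model <- function(object, X) {
  K <- object$n_classes
  scores <- vapply(seq_len(K), function(k) {
    log(object$prior[k]) -
      0.5 * mahalanobis_chol(X, object$means[k, ], object$chol)
  }, numeric(nrow(X)))
  softmax_rows(matrix(scores, nrow = nrow(X)))
}

# Cholesky of a covariance with a ridge fallback for singular matrices:
# eps = 1e-8 * mean diagonal, escalated tenfold until the factorization
# succeeds. Returns the (possibly ridged) matrix and its upper factor.
safe_chol <- function(sigma) {
  u <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(u)) {
    eps <- 1e-8 * mean(diag(sigma))
    if (eps <= 0) eps <- 1e-8
    repeat {
      u <- tryCatch(chol(sigma + eps * diag(nrow(sigma))),
                    error = function(e) NULL)
      if (!is.null(u)) break
      eps <- eps * 10
      if (eps > 1e6) stop("covariance could not be regularized", call. = FALSE)
    }
    warning("singular pooled covariance; ridge ", format(eps),
            " added to the diagonal", call. = FALSE)
    sigma <- sigma + eps * diag(nrow(sigma))
  }
  list(sigma = sigma, u = u)
}

# Squared Mahalanobis distances of the rows of X from mu, given the upper
# Cholesky factor of the covariance.
mahalanobis_chol <- function(X, mu, u) {
  z <- backsolve(u, t(X) - mu, transpose = TRUE)
  colSums(z^2)
}

# Multivariate-normal log density via a precomputed Cholesky factor.
dmvnorm_chol_log <- function(X, mu, u) {
  p <- ncol(X)
  -0.5 * (mahalanobis_chol(X, mu, u) + 2 * sum(log(diag(u))) +
            p * log(2 * pi))
}
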