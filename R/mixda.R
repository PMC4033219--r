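#' Mixture discriminant analysis
#'
#' Models each known class as a mixture of Gaussian subclasses with one
#' covariance matrix shared across all subclasses of all classes:
#' `p(x | k) = sum_r pi_kr * phi(x; mu_kr, Sigma)`. Parameters (subclass
#' means, within-class mixing proportions, shared covariance) are estimated
#' by EM over within-class subclass responsibilities; the observed-data
#' log-likelihood is non-decreasing across iterations. Class posteriors are
#' `prior_k * p(x | k)` renormalized, with priors taken as training class
#' frequencies. The fitted model also exposes per-observation subclass
#' responsibilities — the latent-subgroup readout that distinguishes this
#' method from the other four.
#'
#' Initialization is deterministic: within each class, the first subclass
#' centre is the observation nearest the class mean and each further centre
#' is the observation farthest from those already chosen (farthest-point
#' seeding), followed by a hard nearest-centre assignment. A subclass whose
#' responsibility mass collapses to zero is re-seeded at the in-class point
#' farthest from the class mean, with a warning.
#'
#' @inheritParams fit_lda
#' @param config A [method_config()]; `config$mixda` holds `em_tolerance`
#'   (threshold on the change in observed-data log-likelihood between
#'   iterations, default 5e-5; a scale-free relative criterion stops on EM
#'   plateaus before well-separated subclasses unmix), `em_max_iterations`
#'   (default 100) and `subclasses_per_class` (default 2). With one subclass
#'   per class the model reduces exactly to [fit_lda()].
#' @return A fitted classifier with components `pi` (K x R mixing
#'   proportions), `means` (K x R x p array), `sigma`, `prior`, `loglik`
#'   (per-iteration trace), `responsibilities` (n x R, training rows) and
#'   `subclass` (hard subclass assignment of the training rows).
#' @export
fit_mixda <- function(train, config = method_config()) {
  tr <- as_training(train)
  n <- nrow(tr$X); p <- ncol(tr$X); K <- tr$K
  R <- as.integer(config$mixda$subclasses_per_class)
  nk <- tabulate(tr$y, K)
  if (any(nk < R))
    stop("every class needs at least ", R, " observations", call. = FALSE)
  prior <- nk / n
  rows_k <- lapply(seq_len(K), function(k) which(tr$y == k))
  class_mean <- t(vapply(rows_k, function(r) colMeans(tr$X[r, , drop = FALSE]),
                         numeric(p)))

  # deterministic farthest-point seeding + hard assignment
  resp <- matrix(0, n, R)
  mu <- array(0, dim = c(K, R, p))
  for (k in seq_len(K)) {
    Xk <- tr$X[rows_k[[k]], , drop = FALSE]
    d0 <- rowSums(sweep(Xk, 2, class_mean[k, ])^2)
    seeds <- which.min(d0)
    if (R > 1) {
      mind <- rowSums(sweep(Xk, 2, Xk[seeds[1], ])^2)
      for (r in 2:R) {
        seeds <- c(seeds, which.max(mind))
        mind <- pmin(mind, rowSums(sweep(Xk, 2, Xk[seeds[r], ])^2))
      }
    }
    centre_d <- vapply(seeds, function(s)
      rowSums(sweep(Xk, 2, Xk[s, ])^2), numeric(nrow(Xk)))
    assign_r <- max.col(-matrix(centre_d, nrow = nrow(Xk)),
                        ties.method = "first")
    resp[cbind(rows_k[[k]], assign_r)] <- 1
  }

  Xk_list <- lapply(rows_k, function(r) tr$X[r, , drop = FALSE])
  ss_total <- crossprod(tr$X)          # sum_i x x' ; reused every iteration
  pi_kr <- matrix(0, K, R)
  loglik <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  reseeded <- FALSE
  for (it in seq_len(config$mixda$em_max_iterations)) {
    # M-step. Because responsibilities sum to 1 per row, the shared
    # covariance is the total scatter minus the weighted subclass-mean
    # scatter: sigma = (sum_i x x' - sum_kr sw_kr mu_kr mu_kr') / n.
    mean_scatter <- matrix(0, p, p)
    for (k in seq_len(K)) {
      Xk <- Xk_list[[k]]
      sw <- colSums(resp[rows_k[[k]], , drop = FALSE])
      dead <- sw < 1e-8
      if (any(dead)) {                     # collapsed subclass: re-seed
        far <- which.max(rowSums(sweep(Xk, 2, class_mean[k, ])^2))
        for (r in which(dead)) {
          mu[k, r, ] <- Xk[far, ]
          sw[r] <- 1
        }
        reseeded <- TRUE
      }
      mk <- crossprod(Xk, resp[rows_k[[k]], , drop = FALSE])  # p x R
      for (r in seq_len(R))
        if (!dead[r]) mu[k, r, ] <- mk[, r] / sw[r]
      pi_kr[k, ] <- sw / sum(sw)
      muk <- matrix(mu[k, , ], nrow = R)
      mean_scatter <- mean_scatter + crossprod(muk * sqrt(sw))
    }
    sigma <- (ss_total - mean_scatter) / n
    ch <- safe_chol(sigma)
    sigma <- ch$sigma

    # E-step in whitened coordinates: one triangular solve per class.
    u_inv <- backsolve(ch$u, diag(p))
    const <- -0.5 * (p * log(2 * pi) + 2 * sum(log(diag(ch$u))))
    ll <- 0
    for (k in seq_len(K)) {
      Zk <- Xk_list[[k]] %*% u_inv
      Wk <- matrix(mu[k, , ], nrow = R) %*% u_inv
      logd <- const - 0.5 * (rowSums(Zk^2) - 2 * tcrossprod(Zk, Wk)) +
        rep(log(pmax(pi_kr[k, ], 1e-300)) - 0.5 * rowSums(Wk^2),
            each = nrow(Zk))
      logd <- matrix(logd, nrow = nrow(Zk))
      m <- logd[cbind(seq_len(nrow(logd)),
                      max.col(logd, ties.method = "first"))]
      lse <- m + log(rowSums(exp(logd - m)))
      ll <- ll + sum(lse)
      resp[rows_k[[k]], ] <- exp(logd - lse)
    }
    loglik <- c(loglik, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= config$mixda$em_tolerance) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (reseeded)
    warning("one or more subclasses collapsed and were re-seeded",
            call. = FALSE)
  new_classifier("mixda",
                 list(pi = pi_kr, means = mu, sigma = sigma, chol = ch$u,
                      prior = prior, loglik = loglik, converged = converged,
                      n_iter = length(loglik), responsibilities = resp,
                      subclass = max.col(resp, ties.method = "first")),
                 n_classes = K, p = p)
}

#' @export
posterior_matrix.mixda_model <- function(object, X) {
  K <- object$n_classes
  R <- ncol(object$pi)
  scores <- vapply(seq_len(K), function(k) {
    logd <- vapply(seq_len(R), function(r)
      log(pmax(object$pi[k, r], 1e-300)) +
        dmvnorm_chol_log(X, object$means[k, r, ], object$chol),
      numeric(nrow(X)))
    logd <- matrix(logd, nrow = nrow(X))
    m <- apply(logd, 1, max)
    log(object$prior[k]) + m + log(rowSums(exp(logd - m)))
  }, numeric(nrow(X)))
  softmax_rows(matrix(scores, nrow = nrow(X)))
}
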