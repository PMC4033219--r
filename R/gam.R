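#' Additive logistic (GAM) classifier
#'
#' Fits an additive logistic model per class: the logit of class membership
#' is `alpha + sum_j f_j(x_j)` with each `f_j` a cubic regression spline at
#' a fixed target of 4 degrees of freedom per predictor. With two classes a
#' single binomial model is fitted; with more, one-vs-rest models are fitted
#' and the class scores renormalized to posterior probabilities. The
#' penalized-likelihood iterations stop when the relative deviance change
#' falls below `epsilon` (default 7e-7) or at the iteration cap (default
#' 30); a non-converged fit is returned as-is, mirroring a fixed iteration
#' budget. Constant predictor columns contribute nothing and are dropped
#' from the additive predictor; columns with very few distinct values enter
#' linearly.
#'
#' @inheritParams fit_lda
#' @param config A [method_config()]; `config$gam` holds `epsilon`,
#'   `max_iterations` and the per-predictor spline `df`.
#' @return A fitted classifier wrapping one `mgcv::gam` fit per modeled
#'   class.
#' @export
fit_gam <- function(train, config = method_config()) {
  tr <- as_training(train)
  K <- tr$K
  df <- data.frame(tr$X)
  terms <- character(0)
  for (v in colnames(df)) {
    nu <- length(unique(df[[v]]))
    if (nu < 2) next                       # constant column: no contribution
    if (nu < 4) { terms <- c(terms, v); next }
    k <- min(config$gam$df + 1, nu - 1)
    terms <- c(terms,
               if (k >= 3) sprintf("s(%s, bs = \"cr\", k = %d, fx = TRUE)",
                                   v, k) else v)
  }
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  ctrl <- mgcv::gam.control(epsilon = config$gam$epsilon,
                            maxit = config$gam$max_iterations)
  model_classes <- if (K == 2) 2L else seq_len(K)
  fits <- lapply(model_classes, function(k) {
    df$.y <- as.numeric(tr$y == k)
    mgcv::gam(stats::as.formula(paste(".y ~", rhs)), family = stats::binomial(),
              data = df, control = ctrl)
  })
  new_classifier("gam", list(fits = fits, model_classes = model_classes,
                             varnames = colnames(tr$X)),
                 n_classes = K, p = ncol(tr$X))
}

#' @export
posterior_matrix.gam_model <- function(object, X) {
  nd <- data.frame(X)
  colnames(nd) <- object$varnames
  probs <- vapply(object$fits, function(f)
    as.numeric(stats::predict(f, newdata = nd, type = "response")),
    numeric(nrow(nd)))
  probs <- matrix(probs, nrow = nrow(nd))
  if (object$n_classes == 2) {
    post <- cbind(1 - probs[, 1], probs[, 1])
  } else {
    tot <- rowSums(probs)
    zero <- tot <= 0
    tot[zero] <- 1
    post <- probs / tot
    post[zero, ] <- 1 / object$n_classes
  }
  post
}
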