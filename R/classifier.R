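#' Hyperparameter configuration for the five classification methods
#'
#' Defaults follow the benchmark settings: LDA priors estimated from the
#' data; CART deviance splitting with a reduction threshold of 0.01 of the
#' root deviance and a minimum child size of 10; GAM local-scoring epsilon
#' 7e-7 with at most 30 iterations and cubic splines at 4 target df per
#' predictor; mixture discriminant analysis with 2 Gaussian subclasses per
#' class, EM tolerance 5e-5 and at most 100 EM iterations.
#'
#' @param lda,lr,cart,gam,mixda Named lists of per-method overrides; see
#'   Details.
#' @details Recognized fields: `lda$prior` (`"data"` or `"uniform"`);
#'   `lr$tol`, `lr$max_iter`; `cart$min_deviance_fraction`,
#'   `cart$min_node_size`; `gam$epsilon`, `gam$max_iterations`, `gam$df`;
#'   `mixda$em_tolerance`, `mixda$em_max_iterations`,
#'   `mixda$subclasses_per_class`.
#' @return An object of class `method_config`.
#' @export
#' @examples
#' method_config(mixda = list(subclasses_per_class = 3))
method_config <- function(lda = list(), lr = list(), cart = list(),
                          gam = list(), mixda = list()) {
  cfg <- list(
    lda = list(prior = "data"),
    lr = list(tol = 1e-8, max_iter = 50),
    cart = list(min_deviance_fraction = 0.01, min_node_size = 10),
    gam = list(epsilon = 7e-7, max_iterations = 30, df = 4),
    mixda = list(em_tolerance = 5e-5, em_max_iterations = 100,
                 subclasses_per_class = 2)
  )
  for (m in names(cfg)) {
    ov <- get(m)
    bad <- setdiff(names(ov), names(cfg[[m]]))
    if (length(bad))
      stop("unknown ", m, " option(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    cfg[[m]][names(ov)] <- ov
  }
  with(cfg, {
    stopifnot(lr$tol > 0, lr$max_iter >= 1,
              cart$min_deviance_fraction >= 0, cart$min_node_size >= 1,
              gam$epsilon > 0, gam$max_iterations >= 1, gam$df >= 1,
              mixda$em_tolerance > 0, mixda$em_max_iterations >= 1,
              mixda$subclasses_per_class >= 1)
  })
  if (!cfg$lda$prior %in% c("data", "uniform"))
    stop("`lda$prior` must be \"data\" or \"uniform\"", call. = FALSE)
  structure(cfg, class = "method_config")
}

# Extract (X, y, K) from a labeled_dataset or an (X, group) list; every
# class 1..K must be present in the training labels.
as_training <- function(train) {
  if (inherits(train, "labeled_dataset")) {
    X <- train$X; y <- train$group; K <- train$n_groups
  } else if (is.list(train) && !is.null(train$X) && !is.null(train$group)) {
    X <- as.matrix(train$X); y <- as.integer(train$group); K <- max(y)
  } else stop("`train` must be a labeled_dataset or a list with X and group",
              call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (K < 2) stop("training data must contain at least 2 classes",
                  call. = FALSE)
  missing <- setdiff(seq_len(K), unique(y))
  if (length(missing))
    stop("class(es) absent from training data: ",
         paste(missing, collapse = ", "), call. = FALSE)
  list(X = X, y = y, K = as.integer(K))
}

new_classifier <- function(method, fit, n_classes, p) {
  structure(c(list(method = method, n_classes = as.integer(n_classes),
                   p = as.integer(p)), fit),
            class = c(paste0(method, "_model"), "subgroup_classifier"))
}

#' @export
print.subgroup_classifier <- function(x, ...) {
  cat("<", x$method, " classifier: ", x$n_classes, " classes, ",
      x$p, " predictors>\n", sep = "")
  invisible(x)
}

#' Predict class labels and posterior probabilities
#'
#' Uniform prediction contract for all five classifiers: posterior rows are
#' nonnegative and sum to 1; the predicted label is the posterior argmax
#' with ties broken to the lowest class index.
#'
#' @param object A fitted classifier (from [fit_lda()],
#'   [fit_multinomial_lr()], [fit_cart()], [fit_gam()] or [fit_mixda()]).
#' @param newdata Numeric matrix (or [labeled_dataset()]) with the same
#'   number of columns as the training predictors.
#' @param ... Unused.
#' @return A list with `class` (integer labels, length n) and `posterior`
#'   (n x K matrix).
#' @export
predict.subgroup_classifier <- function(object, newdata, ...) {
  if (inherits(newdata, "labeled_dataset")) newdata <- newdata$X
  X <- as.matrix(newdata)
  if (ncol(X) != object$p)
    stop("`newdata` has ", ncol(X), " columns; model was fitted with ",
         object$p, call. = FALSE)
  if (nrow(X) == 0) {
    return(list(class = integer(0),
                posterior = matrix(numeric(0), 0, object$n_classes)))
  }
  post <- posterior_matrix(object, X)
  list(class = max.col(post, ties.method = "first"), posterior = post)
}

# Internal generic: n x K posterior matrix for a fitted model.
posterior_matrix <- function(object, X) UseMethod("posterior_matrix")

# Row-wise softmax of a matrix of (unnormalized) log scores.
softmax_rows <- function(logit) {
  m <- apply(logit, 1, max)
  e <- exp(logit - m)
  e / rowSums(e)
}
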