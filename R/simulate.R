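#' Labeled dataset container
#'
#' Bundles the predictor matrix with the known-group labels (visible to the
#' classifiers) and the latent subgroup labels (hidden from them; kept for
#' diagnostics).
#'
#' @param X Numeric n x p matrix of predictors.
#' @param group Integer vector of known-group labels in `1..n_groups`.
#' @param subgroup Integer vector of latent subgroup labels in `{1, 2}`.
#' @param role `"train"` or `"cv"`.
#' @param n_groups Number of known groups the labels are drawn from.
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(X, group, subgroup = rep(1L, nrow(X)),
                            role = c("train", "cv"),
                            n_groups = max(group)) {
  role <- match.arg(role)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (length(group) != nrow(X) || length(subgroup) != nrow(X))
    stop("label vectors must have one entry per row of `X`", call. = FALSE)
  structure(list(X = X, group = as.integer(group),
                 subgroup = as.integer(subgroup), role = role,
                 n_groups = as.integer(n_groups)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("Labeled dataset (", x$role, "): ", nrow(x$X), " x ", ncol(x$X),
      ", ", x$n_groups, " known groups\n", sep = "")
  print(table(group = x$group, subgroup = x$subgroup))
  invisible(x)
}

#' @export
as.data.frame.labeled_dataset <- function(x, ...) {
  data.frame(x$X, group = x$group, subgroup = x$subgroup, role = x$role,
             stringsAsFactors = FALSE)
}

#' Write a labeled dataset to CSV
#'
#' Columns `x1..xp, group, subgroup, role`.
#'
#' @param dataset A [labeled_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}

# Upper factor U with t(U) %*% U == sigma. Cholesky when possible, symmetric
# eigen square root for PSD-but-singular matrices; hard error (naming the
# eigenvalue) when sigma is indefinite.
cov_factor <- function(sigma) {
  sigma <- (sigma + t(sigma)) / 2
  u <- tryCatch(chol(sigma), error = function(e) NULL)
  if (!is.null(u)) return(u)
  e <- eigen(sigma, symmetric = TRUE)
  tol <- 1e-8 * max(abs(e$values))
  if (min(e$values) < -tol)
    stop("covariance is not positive semi-definite: eigenvalue ",
         format(min(e$values)), call. = FALSE)
  ev <- pmax(e$values, 0)
  diag(sqrt(ev)) %*% t(e$vectors)
}

# One dataset drawn with fixed per-cell counts; rows in (group, subgroup)
# block order. A single rnorm call per dataset keeps the draw order stable,
# so s = 0 designs are bit-identical to a homogeneous-group simulation.
simulate_dataset <- function(pop, counts, role) {
  n <- sum(counts)
  p <- ncol(pop$means)
  cell_n <- as.integer(t(counts))      # cells in (g1s1, g1s2, g2s1, ...) order
  group <- rep(pop$group, cell_n)
  subgroup <- rep(pop$subgroup, cell_n)
  u <- cov_factor(pop$covariance)
  X <- matrix(stats::rnorm(n * p), n, p) %*% u +
    pop$means[rep(seq_along(cell_n), cell_n), , drop = FALSE]
  colnames(X) <- colnames(pop$means)
  labeled_dataset(X, group, subgroup, role, n_groups = max(pop$group))
}

#' Simulate a paired training / cross-validation sample
#'
#' Draws two independent datasets of the same size from the same population:
#' a training sample and a cross-validation (CV) sample. Observations are
#' correlated multivariate normal (matrix square root of the shared
#' covariance applied to independent standard-normal draws) with fixed
#' per-(group, subgroup) counts from [allocate_sizes()]. The same
#' `(design, seed)` always reproduces the identical pair.
#'
#' @param design A [simulation_design()].
#' @param seed Integer seed for the replicate.
#' @return A list with elements `train` and `cv`, each a [labeled_dataset()].
#' @export
#' @examples
#' pair <- simulate_pair(simulation_design(3, 150, delta = 0.5, s = 0.1),
#'                       seed = 7)
#' table(pair$train$group)
simulate_pair <- function(design, seed) {
  stopifnot(inherits(design, "simulation_design"))
  pop <- make_population(design)
  counts <- allocate_sizes(design)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  list(train = simulate_dataset(pop, counts, "train"),
       cv = simulate_dataset(pop, counts, "cv"))
}
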