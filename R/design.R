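#' Population correlation matrix for the five simulated predictors
#'
#' Correlations among the first five WAIS-III subscales, used as the default
#' population correlation structure of the simulated predictors. All
#' population standard deviations are 1, so this matrix is also the shared
#' covariance matrix of every group and subgroup.
#'
#' @return A symmetric 5 x 5 correlation matrix with dimnames `x1`..`x5`.
#' @export
#' @examples
#' wais_correlations()
wais_correlations <- function() {
  r <- matrix(c(
    1.00, 0.76, 0.58, 0.43, 0.39,
    0.76, 1.00, 0.57, 0.36, 0.49,
    0.58, 0.57, 1.00, 0.45, 0.74,
    0.43, 0.36, 0.45, 1.00, 0.69,
    0.39, 0.49, 0.74, 0.69, 1.00), nrow = 5, byrow = TRUE)
  dimnames(r) <- list(paste0("x", 1:5), paste0("x", 1:5))
  r
}

#' Specify one cell of the simulation design
#'
#' A design cell fixes the six manipulated factors of the study: number of
#' known groups, total sample size, known-group size proportions, latent
#' subgroup proportions (applied within every group), the standardized mean
#' difference `delta` separating adjacent known groups, and the standardized
#' separation `s` between the two latent subgroups within each group. Both
#' `delta` and `s` are on the unit-SD scale (population SDs are all 1).
#'
#' @param n_groups Number of known groups (2 or 3).
#' @param total_n Total sample size across all groups.
#' @param group_proportions Vector of known-group proportions, length
#'   `n_groups`, summing to 1. Default: equal groups.
#' @param subgroup_proportions Pair of latent-subgroup proportions applied
#'   within every group, summing to 1. The first element is the subgroup
#'   whose mean is farthest from the adjacent group (the "base" subgroup);
#'   under an unequal ratio the larger share goes there.
#' @param delta Standardized mean difference between adjacent known groups
#'   (applied to every predictor); must be >= 0.
#' @param s Standardized separation between the two subgroup means within a
#'   group (applied to every predictor); must be >= 0. `s = 0` is the
#'   homogeneous control with no subgroup structure.
#' @param n_predictors Number of predictors (default 5).
#' @param correlation Population correlation matrix of the predictors;
#'   symmetric, unit diagonal, positive semi-definite. Default
#'   [wais_correlations()].
#' @return An object of class `simulation_design`.
#' @export
#' @examples
#' simulation_design(n_groups = 3, total_n = 150, delta = 0.5, s = 0.1)
simulation_design <- function(n_groups = 3,
                              total_n = 150,
                              group_proportions = NULL,
                              subgroup_proportions = c(0.5, 0.5),
                              delta = 0.5,
                              s = 0,
                              n_predictors = 5,
                              correlation = wais_correlations()) {
  if (!n_groups %in% c(2L, 3L))
    stop("`n_groups` must be 2 or 3", call. = FALSE)
  n_groups <- as.integer(n_groups)
  if (is.null(group_proportions))
    group_proportions <- rep(1 / n_groups, n_groups)
  if (length(group_proportions) != n_groups ||
      abs(sum(group_proportions) - 1) > 1e-8 || any(group_proportions < 0))
    stop("`group_proportions` must be ", n_groups,
         " nonnegative fractions summing to 1", call. = FALSE)
  if (length(subgroup_proportions) != 2 ||
      abs(sum(subgroup_proportions) - 1) > 1e-8 ||
      any(subgroup_proportions < 0))
    stop("`subgroup_proportions` must be 2 nonnegative fractions summing to 1",
         call. = FALSE)
  if (!is.numeric(total_n) || total_n < 1)
    stop("`total_n` must be a positive integer", call. = FALSE)
  if (delta < 0) stop("`delta` must be >= 0", call. = FALSE)
  if (s < 0) stop("`s` must be >= 0", call. = FALSE)
  correlation <- as.matrix(correlation)
  if (nrow(correlation) != n_predictors || ncol(correlation) != n_predictors)
    stop("`correlation` must be ", n_predictors, " x ", n_predictors,
         call. = FALSE)
  if (max(abs(correlation - t(correlation))) > 1e-8)
    stop("`correlation` must be symmetric", call. = FALSE)
  if (max(abs(diag(correlation) - 1)) > 1e-8)
    stop("`correlation` must have unit diagonal", call. = FALSE)
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("`correlation` is not positive semi-definite: eigenvalue ",
         format(min(ev)), call. = FALSE)
  structure(list(
    n_groups = n_groups,
    total_n = as.integer(round(total_n)),
    group_proportions = as.numeric(group_proportions),
    subgroup_proportions = as.numeric(subgroup_proportions),
    delta = delta,
    s = s,
    n_predictors = as.integer(n_predictors),
    correlation = correlation
  ), class = "simulation_design")
}

#' @export
print.simulation_design <- function(x, ...) {
  cat("Simulation design:", x$n_groups, "known groups x 2 latent subgroups\n")
  cat("  total n:", x$total_n,
      " group proportions:", paste(signif(x$group_proportions, 3),
                                   collapse = "/"),
      " subgroup proportions:", paste(signif(x$subgroup_proportions, 3),
                                      collapse = "/"), "\n")
  cat("  group separation delta:", x$delta,
      " subgroup separation s:", x$s, "\n")
  cat("  predictors:", x$n_predictors, "(shared correlation matrix)\n")
  invisible(x)
}

#' Resolve a design cell into its generative population
#'
#' Group `g` (1-indexed) has base mean `(g - 1) * delta` on every predictor.
#' Each group's second subgroup is displaced by `s` toward the adjacent
#' group: `+s` for group 1 (and any middle group), `-s` for the last group.
#' The first ("base") subgroup therefore always sits farthest from the other
#' known group(s). All subgroups share the design correlation matrix as
#' their covariance (unit SDs).
#'
#' @param design A [simulation_design()].
#' @return An object of class `population_spec`: a list with `means` (one
#'   row per (group, subgroup) cell), `weights` (sampling probability of each
#'   cell, summing to 1), `group`, `subgroup` (cell indices), and
#'   `covariance`.
#' @export
#' @examples
#' pop <- make_population(simulation_design(2, 100, delta = 0.8, s = 0.05))
#' pop$means[, 1]  # per-cell means on the first predictor: 0, 0.05, 0.8, 0.75
make_population <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  g_idx <- rep(seq_len(design$n_groups), each = 2)
  s_idx <- rep(1:2, design$n_groups)
  base <- (g_idx - 1) * design$delta
  # displacement of subgroup 2, toward the adjacent group
  dir <- ifelse(g_idx < design$n_groups, 1, -1)
  shift <- ifelse(s_idx == 2, design$s * dir, 0)
  mu <- matrix(base + shift, nrow = length(g_idx),
               ncol = design$n_predictors)
  colnames(mu) <- paste0("x", seq_len(design$n_predictors))
  rownames(mu) <- paste0("g", g_idx, "s", s_idx)
  w <- design$group_proportions[g_idx] * design$subgroup_proportions[s_idx]
  structure(list(means = mu, weights = w, group = g_idx, subgroup = s_idx,
                 covariance = design$correlation),
            class = "population_spec")
}

#' Allocate fixed per-(group, subgroup) sample counts
#'
#' Realizes the design proportions as exact integer counts so that group and
#' subgroup size ratios hold in every replicate (counts are fixed, not
#' multinomially drawn). Fractional seats are resolved by largest remainder;
#' remainder ties go to the cell with the larger target proportion, then to
#' the lower index. Within each group the larger subgroup is the base
#' subgroup (the one farthest from the adjacent known group).
#'
#' @param design A [simulation_design()].
#' @return An integer matrix with one row per known group and two columns
#'   (subgroups); entries sum to `design$total_n`.
#' @export
#' @examples
#' d <- simulation_design(3, 150, group_proportions = c(0.6, 0.2, 0.2),
#'                        subgroup_proportions = c(0.75, 0.25))
#' allocate_sizes(d)  # group 1: 68 + 22
allocate_sizes <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  if (design$total_n < 1) stop("`total_n` must be >= 1", call. = FALSE)
  n_group <- largest_remainder(design$total_n, design$group_proportions)
  counts <- t(vapply(n_group, largest_remainder,
                     integer(2), props = design$subgroup_proportions))
  dimnames(counts) <- list(paste0("group", seq_len(design$n_groups)),
                           c("subgroup1", "subgroup2"))
  if (any(counts == 0))
    warning("some (group, subgroup) cells have zero allocated observations",
            call. = FALSE)
  counts
}

# Largest-remainder apportionment of n seats to `props`;
# ties by larger proportion, then lower index.
largest_remainder <- function(n, props) {
  quota <- n * props
  base <- floor(quota)
  left <- as.integer(round(n - sum(base)))
  if (left > 0) {
    rem <- quota - base
    ord <- order(-rem, -props, seq_along(props))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}
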