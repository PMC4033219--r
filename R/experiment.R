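#' Define a factorial simulation experiment
#'
#' The full factorial cross of the study factors: total sample size,
#' known-group size ratio, latent-subgroup size ratio, known-group
#' separation `delta`, and subgroup separation (`overlap`), for 2 or 3
#' known groups. Defaults are the three-group study grid: N in
#' {150, 300, 750}, group ratios equal and 60/20/20, subgroup ratios equal
#' and 75/25, delta in {0.2, 0.5, 0.8}, overlap in
#' {0, 0.05, 0.10, 0.15, 0.20}, 1000 replicates per cell.
#'
#' @param n_groups 2 or 3.
#' @param total_n Vector of total sample sizes.
#' @param group_ratio Character vector from `"equal"`, `"unequal"`
#'   (75/25 for two groups, 60/20/20 for three).
#' @param subgroup_ratio Character vector from `"equal"`, `"75/25"`.
#' @param delta Vector of known-group standardized mean differences.
#' @param overlap Vector of subgroup separations `s`.
#' @param methods Classifiers to run; subset of
#'   `c("lda", "lr", "cart", "gam", "mixda")`.
#' @param replicates Replicates per cell (>= 1).
#' @param seed Master seed; each (cell, replicate) derives its own seed
#'   from it via [child_seed()].
#' @param config A [method_config()].
#' @return An object of class `experiment_grid`; `$cells` holds one row per
#'   design cell in seed order.
#' @export
#' @examples
#' experiment_grid(replicates = 2, methods = c("lda", "cart"))
experiment_grid <- function(n_groups = 3,
                            total_n = if (n_groups == 3) c(150, 300, 750)
                                      else c(100, 200, 500),
                            group_ratio = c("equal", "unequal"),
                            subgroup_ratio = c("equal", "75/25"),
                            delta = c(0.2, 0.5, 0.8),
                            overlap = c(0, 0.05, 0.10, 0.15, 0.20),
                            methods = c("lda", "lr", "cart", "gam", "mixda"),
                            replicates = 1000,
                            seed = 1,
                            config = method_config()) {
  known <- c("lda", "lr", "cart", "gam", "mixda")
  bad <- setdiff(methods, known)
  if (length(bad))
    stop("unknown method(s): ", paste(bad, collapse = ", "), call. = FALSE)
  stopifnot(replicates >= 1, length(total_n) >= 1, length(delta) >= 1,
            length(overlap) >= 1)
  group_ratio <- match.arg(group_ratio, c("equal", "unequal"),
                           several.ok = TRUE)
  subgroup_ratio <- match.arg(subgroup_ratio, c("equal", "75/25"),
                              several.ok = TRUE)
  cells <- expand.grid(total_n = total_n, group_ratio = group_ratio,
                       subgroup_ratio = subgroup_ratio, delta = delta,
                       overlap = overlap, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  cells$cell <- seq_len(nrow(cells))
  structure(list(n_groups = as.integer(n_groups), cells = cells,
                 methods = methods, replicates = as.integer(replicates),
                 seed = as.integer(seed), config = config),
            class = "experiment_grid")
}

#' @export
print.experiment_grid <- function(x, ...) {
  cat("Experiment grid:", nrow(x$cells), "cells x", x$replicates,
      "replicates,", x$n_groups, "known groups\n")
  cat("  methods:", paste(x$methods, collapse = ", "),
      " master seed:", x$seed, "\n")
  invisible(x)
}

#' Group / subgroup proportions for a named ratio level
#'
#' @param ratio `"equal"`, `"unequal"` (group level) or `"75/25"`.
#' @param n_groups Number of groups (group-level ratios only).
#' @return Numeric proportion vector.
#' @export
ratio_proportions <- function(ratio, n_groups = 2) {
  switch(ratio,
         equal = rep(1 / n_groups, n_groups),
         unequal = if (n_groups == 3) c(0.6, 0.2, 0.2) else c(0.75, 0.25),
         "75/25" = c(0.75, 0.25),
         stop("unknown ratio level: ", ratio, call. = FALSE))
}

#' Derive a per-replicate child seed
#'
#' Deterministic integer mix of (master seed, cell index, replicate index)
#' by two rounds of a 69069 multiplicative congruential step modulo
#' 2^31 - 1, so that every (cell, replicate) has its own reproducible
#' random-number stream and cells can be re-run independently.
#'
#' @param master Master seed.
#' @param cell Cell index (1-based).
#' @param rep Replicate index (1-based).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(master, cell, rep) {
  m <- 2147483647
  h <- as.numeric(master) %% m
  h <- (h * 69069 + as.numeric(cell)) %% m
  h <- (h * 69069 + as.numeric(rep)) %% m
  as.integer(h)
}

cell_design <- function(grid, ci) {
  row <- grid$cells[ci, ]
  simulation_design(
    n_groups = grid$n_groups,
    total_n = row$total_n,
    group_proportions = ratio_proportions(row$group_ratio, grid$n_groups),
    subgroup_proportions = ratio_proportions(row$subgroup_ratio),
    delta = row$delta,
    s = row$overlap)
}

fit_one <- function(method, train, config) {
  switch(method,
         lda = fit_lda(train, config),
         lr = fit_multinomial_lr(train, config),
         cart = fit_cart(train, config),
         gam = fit_gam(train, config),
         mixda = fit_mixda(train, config))
}

#' Run the factorial experiment
#'
#' For every (cell, replicate): derives a child seed, simulates a paired
#' training / cross-validation sample, fits every requested method on the
#' training sample (known-group labels only — latent subgroup labels are
#' never shown to a classifier), and records overall and by-group
#' misclassification rates on both samples. A failure of one method is
#' recorded as missing (`NA` rates) without aborting the cell; fit-time
#' warnings (e.g. separation, non-convergence) are muffled.
#'
#' @param grid An [experiment_grid()].
#' @param verbose Print per-cell progress.
#' @return A tidy data frame with one row per
#'   (cell, replicate, method, role): design factors, `seed`, `overall`
#'   rate, and `group1..groupK` rates.
#' @export
#' @examples
#' g <- experiment_grid(total_n = 150, group_ratio = "equal",
#'                      subgroup_ratio = "equal", delta = 0.5, overlap = 0.1,
#'                      methods = c("lda", "cart"), replicates = 2)
#' run_grid(g)
run_grid <- function(grid, verbose = FALSE) {
  stopifnot(inherits(grid, "experiment_grid"))
  n_cells <- nrow(grid$cells)
  n_methods <- length(grid$methods)
  K <- grid$n_groups
  n_rows <- n_cells * grid$replicates * n_methods * 2L
  out <- list(cell = integer(n_rows), replicate = integer(n_rows),
              seed = integer(n_rows), method = character(n_rows),
              role = character(n_rows), overall = rep(NA_real_, n_rows))
  grates <- matrix(NA_real_, n_rows, K)
  i <- 0L
  for (ci in seq_len(n_cells)) {
    design <- cell_design(grid, ci)
    if (verbose)
      message(sprintf("cell %d/%d: N=%d %s/%s delta=%.2f s=%.2f",
                      ci, n_cells, design$total_n,
                      grid$cells$group_ratio[ci],
                      grid$cells$subgroup_ratio[ci],
                      grid$cells$delta[ci], grid$cells$overlap[ci]))
    for (rep_i in seq_len(grid$replicates)) {
      seed <- child_seed(grid$seed, ci, rep_i)
      pair <- simulate_pair(design, seed)
      for (m in grid$methods) {
        fit <- tryCatch(
          suppressWarnings(suppressMessages(fit_one(m, pair$train,
                                                    grid$config))),
          error = function(e) {
            if (verbose)
              message("  ", m, " failed (cell ", ci, ", replicate ",
                      rep_i, "): ", conditionMessage(e))
            NULL
          })
        for (role in c("train", "cv")) {
          i <- i + 1L
          out$cell[i] <- ci; out$replicate[i] <- rep_i
          out$seed[i] <- seed; out$method[i] <- m; out$role[i] <- role
          if (!is.null(fit)) {
            ds <- pair[[if (role == "train") "train" else "cv"]]
            pred <- predict(fit, ds$X)
            out$overall[i] <- misclassification_overall(pred$class, ds$group)
            grates[i, ] <- misclassification_by_group(pred$class, ds$group,
                                                      seq_len(K))
          }
        }
      }
    }
  }
  res <- data.frame(grid$cells[out$cell, c("cell", "total_n", "group_ratio",
                                           "subgroup_ratio", "delta",
                                           "overlap")],
                    replicate = out$replicate, seed = out$seed,
                    method = out$method, role = out$role,
                    overall = out$overall, row.names = NULL)
  colnames(grates) <- paste0("group", seq_len(K))
  cbind(res, grates)
}

#' Aggregate replicate results into a summary table
#'
#' Mean misclassification rates per design cell and method, where a "cell"
#' is defined by the factors named in `by` (other factors are collapsed by
#' unweighted averaging over replicates). With `by_group = TRUE` each known
#' group's rate is summarized instead of the overall rate.
#'
#' @param results Data frame from [run_grid()].
#' @param by Character vector of factor columns to keep
#'   (e.g. `"overlap"`, or `c("subgroup_ratio", "overlap")`).
#' @param role `"cv"` (default) or `"train"`.
#' @param by_group Summarize per-group rates instead of the overall rate.
#' @return A data frame with the `by` columns, `method`, optionally
#'   `group`, and `rate` (mean over contributing replicates); failed fits
#'   are dropped with a warning when a whole cell is empty.
#' @export
summarize_results <- function(results, by = "overlap", role = "cv",
                              by_group = FALSE) {
  stopifnot(all(by %in% colnames(results)))
  res <- results[results$role == role, , drop = FALSE]
  if (nrow(res) == 0) stop("no rows for role ", role, call. = FALSE)
  if (by_group) {
    gcols <- grep("^group[0-9]+$", colnames(res), value = TRUE)
    long <- do.call(rbind, lapply(gcols, function(g) {
      d <- res[c(by, "method")]
      d$group <- as.integer(sub("group", "", g))
      d$value <- res[[g]]
      d
    }))
    keys <- c(by, "method", "group")
  } else {
    long <- res[c(by, "method")]
    long$value <- res$overall
    keys <- c(by, "method")
  }
  agg <- stats::aggregate(long["value"], long[keys],
                          function(v) mean(v, na.rm = TRUE))
  names(agg)[names(agg) == "value"] <- "rate"
  if (anyNA(agg$rate))
    warning("cell(s) with no successful fits reported as NaN", call. = FALSE)
  agg[do.call(order, unname(agg[keys])), , drop = FALSE]
}

#' Marginal descriptive statistics per method
#'
#' Min, max, median, mean and interquartile range of the per-cell mean
#' rates across the full factor cross (the bottom block of the study's
#' condition table).
#'
#' @inheritParams summarize_results
#' @param factors Columns defining a cell; defaults to all five design
#'   factors.
#' @return A data frame with one row per method.
#' @export
marginal_stats <- function(results, role = "cv",
                           factors = c("total_n", "group_ratio",
                                       "subgroup_ratio", "delta",
                                       "overlap")) {
  cellmeans <- summarize_results(results, by = factors, role = role)
  out <- do.call(rbind, lapply(split(cellmeans, cellmeans$method),
                               function(d) data.frame(
    method = d$method[1],
    min = min(d$rate), max = max(d$rate),
    median = stats::median(d$rate), mean = mean(d$rate),
    iqr = stats::IQR(d$rate))))
  rownames(out) <- NULL
  out
}

#' Pivot a summary so that methods become columns
#'
#' Convenience layout matching the printed condition tables (one column per
#' method, or per method x group).
#'
#' @param summary Data frame from [summarize_results()].
#' @return A wide data frame.
#' @export
pivot_methods <- function(summary) {
  keys <- setdiff(colnames(summary), c("method", "group", "rate"))
  summary$.col <- if ("group" %in% colnames(summary))
    paste0(summary$method, summary$group) else summary$method
  wide <- stats::reshape(summary[c(keys, ".col", "rate")],
                         idvar = keys, timevar = ".col",
                         direction = "wide")
  colnames(wide) <- sub("^rate\\.", "", colnames(wide))
  rownames(wide) <- NULL
  wide
}

#' Write summary tables to disk
#'
#' Writes each summary as CSV (always) and optionally as a plain-text
#' rendering of its method-wide pivot.
#'
#' @param summaries A named list of data frames (or a single data frame).
#' @param dir Output directory (created if missing).
#' @param text Also write a `.txt` rendering.
#' @return Invisibly, the paths written.
#' @export
report_summaries <- function(summaries, dir, text = FALSE) {
  if (is.data.frame(summaries)) summaries <- list(summary = summaries)
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", dir, call. = FALSE)
  paths <- character(0)
  for (nm in names(summaries)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(summaries[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
    if (text && all(c("method", "rate") %in% colnames(summaries[[nm]]))) {
      tp <- file.path(dir, paste0(nm, ".txt"))
      utils::capture.output(print(pivot_methods(summaries[[nm]]),
                                  digits = 3), file = tp)
      paths <- c(paths, tp)
    }
  }
  invisible(paths)
}

#' Read an experiment definition from YAML or JSON
#'
#' The file may contain any argument of [experiment_grid()]
#' (`n_groups`, `total_n`, `group_ratio`, `subgroup_ratio`, `delta`,
#' `overlap`, `methods`, `replicates`, `seed`) plus an optional `config`
#' block of per-method overrides passed to [method_config()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [experiment_grid()].
#' @export
read_experiment_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  spec <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
          else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
          else stop("config must be YAML or JSON", call. = FALSE)
  cfg_over <- spec$config
  spec$config <- NULL
  # YAML sequences with mixed int/float types parse as lists; flatten
  spec <- lapply(spec, function(x) if (is.list(x)) unlist(x) else x)
  known <- setdiff(names(formals(experiment_grid)), "config")
  bad <- setdiff(names(spec), known)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  spec$config <- do.call(method_config, as.list(cfg_over))
  do.call(experiment_grid, spec)
}
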