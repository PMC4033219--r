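#' Overall misclassification rate
#'
#' Number of observations assigned to the wrong known group divided by the
#' total sample size.
#'
#' @param predicted,truth Equal-length label vectors.
#' @return A fraction in `[0, 1]`.
#' @export
#' @examples
#' misclassification_overall(c(1, 2, 2, 1), c(1, 2, 1, 1))  # 0.25
misclassification_overall <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("`predicted` and `truth` must have the same length", call. = FALSE)
  if (length(truth) == 0) stop("empty label vectors", call. = FALSE)
  mean(predicted != truth)
}

#' By-group misclassification rates
#'
#' For each known group, the number of its members classified into another
#' group divided by the group size. The group-size-weighted mean of these
#' rates equals the overall rate.
#'
#' @inheritParams misclassification_overall
#' @param groups Group labels to report, default `1..max(truth)`. A group
#'   with no members in `truth` gets rate `NA` with a warning (and is
#'   excluded from any aggregation).
#' @return Named numeric vector of per-group rates.
#' @export
#' @examples
#' misclassification_by_group(c(1, 1, 2, 2, 2), c(1, 2, 2, 2, 2))
misclassification_by_group <- function(predicted, truth,
                                       groups = seq_len(max(truth))) {
  if (length(predicted) != length(truth))
    stop("`predicted` and `truth` must have the same length", call. = FALSE)
  rates <- vapply(groups, function(g) {
    idx <- truth == g
    if (!any(idx)) return(NA_real_)
    mean(predicted[idx] != g)
  }, numeric(1))
  names(rates) <- paste0("group", groups)
  if (anyNA(rates))
    warning("group(s) with no members: rate undefined (NA): ",
            paste(groups[is.na(rates)], collapse = ", "), call. = FALSE)
  rates
}

#' Increase in misclassification from equal to unequal subgroup ratios
#'
#' Difference in mean misclassification between the unequal (75/25) and the
#' equal subgroup-ratio conditions, per method and subgroup-separation level
#' (and, if present, per known group) — the quantity displayed in the
#' study's equal-vs-75/25 bar figures. Negative values indicate that the
#' unequal condition was *easier* for that method.
#'
#' @param summary_equal,summary_unequal Data frames as returned by
#'   [summarize_results()] restricted to one subgroup-ratio condition each;
#'   both must contain columns `method`, `overlap`, `rate` and cover the
#'   same cells (plus an optional `group` column).
#' @return A data frame with the shared cell columns and `increase`
#'   (unequal minus equal mean rate).
#' @export
subgroup_ratio_increase <- function(summary_equal, summary_unequal) {
  keys <- intersect(c("method", "overlap", "group"), colnames(summary_equal))
  for (d in list(summary_equal, summary_unequal))
    if (!all(c(keys, "rate") %in% colnames(d)))
      stop("summaries must contain columns ",
           paste(c(keys, "rate"), collapse = ", "), call. = FALSE)
  eq <- summary_equal[c(keys, "rate")]
  un <- summary_unequal[c(keys, "rate")]
  merged <- merge(eq, un, by = keys, suffixes = c("_equal", "_unequal"),
                  all = TRUE)
  miss <- is.na(merged$rate_equal) | is.na(merged$rate_unequal)
  if (any(miss)) {
    lab <- apply(merged[miss, keys, drop = FALSE], 1, paste,
                 collapse = " / ")
    stop("cell(s) missing from one summary: ", paste(lab, collapse = "; "),
         call. = FALSE)
  }
  merged$increase <- merged$rate_unequal - merged$rate_equal
  merged[order(merged$method, merged$overlap), c(keys, "increase")]
}
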