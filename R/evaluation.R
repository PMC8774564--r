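#' Relative error in percent
#'
#' `100 * |estimated - truth| / |truth|`, vectorized.
#'
#' @param estimated,truth Numeric vectors (recycled); `truth` must be
#'   nonzero.
#' @return Percentage errors (`>= 0`).
#' @examples
#' relative_error_pct(435.1, 61.8)  # about 604%
#' @export
relative_error_pct <- function(estimated, truth) {
  if (any(truth == 0)) abort("`truth` must be nonzero.")
  100 * abs(estimated - truth) / abs(truth)
}

#' Mean squared error of a fit
#'
#' The sum-of-squares objective normalized by the number of points in the
#' series (per-point mean of squared residuals).
#'
#' @param params Component-parameter data frame (`m0`, `t1_ms`) or an
#'   [ir_fit()] object.
#' @param series Series data frame; defaults to the series stored in an
#'   `ir_fit` object.
#' @return Scalar MSE.
#' @export
mse_of_fit <- function(params, series = NULL) {
  if (inherits(params, "ir_fit")) {
    series <- series %||% params$series
    params <- params$params
  }
  if (is.null(series) || nrow(series) == 0) abort("`series` must be non-empty.")
  ir_objective(series, params) / nrow(series)
}

# All permutations of 1..n in lexicographic order (n <= 7), memoized.
perm_cache <- new.env(parent = emptyenv())
permutations_lex <- function(n) {
  key <- as.character(n)
  if (!is.null(perm_cache[[key]])) return(perm_cache[[key]])
  gen <- function(items) {
    if (length(items) <= 1) return(matrix(items, nrow = 1))
    do.call(rbind, lapply(seq_along(items), function(i)
      cbind(items[i], gen(items[-i]))))
  }
  perm_cache[[key]] <- gen(seq_len(n))
  perm_cache[[key]]
}

#' Match estimated components to ground truth
#'
#' The multi-component model is invariant under permutation of its
#' `(M0, T1)` pairs, so estimated components must be assigned to true
#' components before errors can be computed. The assignment minimizing
#' the total relative T1 error is found by exhaustive search over all
#' permutations (at most 5040 for seven components); ties break to the
#' lexicographically first permutation, making the result deterministic
#' and independent of the input order of the estimates.
#'
#' @param estimated Data frame of estimated parameters (`m0`, `t1_ms`) or
#'   an [ir_fit()] object.
#' @param truth Data frame of true parameters (`m0`, `t1_ms`), same
#'   number of components.
#' @return The estimated components reordered to align with the rows of
#'   `truth`, with the chosen permutation in attribute `"permutation"`.
#' @export
match_components <- function(estimated, truth) {
  if (inherits(estimated, "ir_fit")) estimated <- estimated$params
  check_params(estimated, "estimated")
  check_params(truth, "truth")
  n <- nrow(truth)
  if (nrow(estimated) != n)
    abort(sprintf("component counts differ: %d estimated vs %d true.",
                  nrow(estimated), n))
  # E[i, j] = relative T1 error of estimate i against truth j
  E <- abs(outer(estimated$t1_ms, truth$t1_ms, "-")) /
    rep(abs(truth$t1_ms), each = n)
  perms <- permutations_lex(n)
  # cost of permutation p: sum_j E[p[j], j]
  cost <- perms
  for (j in seq_len(n)) cost[, j] <- E[perms[, j], j]
  totals <- rowSums(cost)
  best <- perms[which.min(totals), ]   # which.min takes the first minimum
  out <- estimated[best, , drop = FALSE]
  out$component <- seq_len(n)
  attr(out, "permutation") <- best
  as_tibble(out)
}

#' Per-coefficient error table of a fit against its ground truth
#'
#' Matches components by minimum total relative T1 error, then reports
#' one row per coefficient (both families, `m0` and `t1`).
#'
#' @inheritParams match_components
#' @return Tibble with `family` (`"m0"`/`"t1"`), `component` (index of
#'   the true component), `truth`, `estimate`, `rel_error_pct`.
#' @export
component_errors <- function(estimated, truth) {
  matched <- match_components(estimated, truth)
  n <- nrow(truth)
  truth_v <- c(truth$m0, truth$t1_ms)
  est_v <- c(matched$m0, matched$t1_ms)
  tibble(family = rep(c("m0", "t1"), each = n),
         component = rep(seq_len(n), 2),
         truth = truth_v,
         estimate = est_v,
         rel_error_pct = relative_error_pct(est_v, truth_v))
}

#' Min / mean / max error summaries by coefficient family
#'
#' Collapses a long error table into the layout of the reported error
#' tables: one row per grouping combination and family with the minimum,
#' mean and maximum relative error.
#'
#' @param errors Tibble with at least `family` and `rel_error_pct`
#'   columns (as produced by [component_errors()] or the experiment
#'   drivers).
#' @param ... Additional grouping columns (tidy-select of bare names),
#'   e.g. `n_starts` or `variance`.
#' @return Tibble with `min_error_pct`, `mean_error_pct`, `max_error_pct`.
#' @export
error_summary <- function(errors, ...) {
  errors |>
    dplyr::group_by(..., .data$family) |>
    dplyr::summarise(min_error_pct = min(.data$rel_error_pct),
                     mean_error_pct = mean(.data$rel_error_pct),
                     max_error_pct = max(.data$rel_error_pct),
                     .groups = "drop")
}
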