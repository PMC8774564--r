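#' Trust-region solver settings
#'
#' Controls the bound-constrained trust-region least-squares iteration.
#' Defaults follow standard trust-region-reflective practice; the trust
#' region lives in the affine-scaled (unit box) coordinates induced by the
#' parameter bounds, so the radius is dimensionless.
#'
#' @param max_iterations Iteration cap per start.
#' @param gradient_tolerance Stop when the Coleman-Li first-order measure
#'   (scaled distance-to-bound times gradient, sup norm) falls below this
#'   times `max(1, objective)`.
#' @param step_tolerance Stop when an accepted step is shorter than
#'   `step_tolerance * (step_tolerance + ||z||)` in scaled coordinates.
#' @param initial_radius Initial trust-region radius (scaled coordinates).
#' @param radius_shrink Factor in (0,1) applied on rejection or poor model
#'   agreement.
#' @param radius_grow Factor > 1 applied after a near-boundary step with
#'   very good model agreement.
#' @param accept_threshold_low,accept_threshold_high Thresholds on the
#'   ratio of actual to predicted reduction: below the low threshold the
#'   radius shrinks (improving steps are still taken), above the high
#'   threshold a boundary step grows the radius.
#' @return A list of class `trf_control`.
#' @export
trf_control <- function(max_iterations = 400L,
                        gradient_tolerance = 1e-8,
                        step_tolerance = 1e-10,
                        initial_radius = 1,
                        radius_shrink = 0.25,
                        radius_grow = 2,
                        accept_threshold_low = 0.25,
                        accept_threshold_high = 0.75) {
  stopifnot(max_iterations >= 1,
            gradient_tolerance > 0, step_tolerance > 0, initial_radius > 0,
            radius_shrink > 0, radius_shrink < 1, radius_grow > 1,
            accept_threshold_low < accept_threshold_high,
            accept_threshold_low > 0, accept_threshold_high < 1)
  structure(list(max_iterations = as.integer(max_iterations),
                 gradient_tolerance = gradient_tolerance,
                 step_tolerance = step_tolerance,
                 initial_radius = initial_radius,
                 radius_shrink = radius_shrink,
                 radius_grow = radius_grow,
                 accept_threshold_low = accept_threshold_low,
                 accept_threshold_high = accept_threshold_high),
            class = "trf_control")
}

#' Box constraints for the component parameters
#'
#' Builds per-component bounds the way the experiments bound the search
#' space: T1 between literature extremes (fat approximately 250 ms, CSF
#' approximately 4000 ms at 3 T) and M0 between a minimum-representation
#' fraction of the data maximum and the data maximum itself.
#'
#' @param series Optional series data frame used to derive the M0 bounds
#'   from the maximum measured magnitude.
#' @param n_components Number of components the bounds apply to.
#' @param t1_range_ms Length-2 vector of T1 bounds in ms.
#' @param m0_upper,m0_lower Explicit M0 bounds (scalar or per component);
#'   when `NULL` they default to `max(magnitude)` and
#'   `m0_lower_frac * max(magnitude)`.
#' @param m0_lower_frac Minimum-representation fraction used for the
#'   default M0 lower bound.
#' @return A list of class `ir_bounds` with fields `m0_lower`, `m0_upper`,
#'   `t1_lower_ms`, `t1_upper_ms`, each of length `n_components`.
#' @export
ir_bounds <- function(series = NULL, n_components,
                      t1_range_ms = c(250, 4000),
                      m0_upper = NULL, m0_lower = NULL,
                      m0_lower_frac = 0.05) {
  n <- as.integer(n_components)
  if (n < 1 || n > 7) abort("`n_components` must be between 1 and 7.")
  if (is.null(m0_upper)) {
    if (is.null(series))
      abort("either `series` or `m0_upper` must be supplied.")
    m0_upper <- max(abs(series$magnitude))
  }
  if (is.null(m0_lower)) m0_lower <- m0_lower_frac * max(m0_upper)
  out <- list(m0_lower = rep_len(m0_lower, n),
              m0_upper = rep_len(m0_upper, n),
              t1_lower_ms = rep_len(t1_range_ms[1], n),
              t1_upper_ms = rep_len(t1_range_ms[2], n))
  if (any(out$m0_lower >= out$m0_upper) || any(out$t1_lower_ms >= out$t1_upper_ms))
    abort("lower bounds must be strictly below upper bounds.")
  if (any(out$t1_lower_ms <= 0)) abort("T1 lower bounds must be positive.")
  structure(out, class = "ir_bounds")
}

bounds_vectors <- function(bounds) {
  list(lower = c(bounds$m0_lower, bounds$t1_lower_ms),
       upper = c(bounds$m0_upper, bounds$t1_upper_ms))
}

#' Uniform random starting points within bounds
#'
#' Draws each coordinate independently from the uniform distribution on
#' its bound interval, one start at a time, so for a fixed RNG state the
#' first `k` rows of a larger draw equal a draw of `k` starts (nested
#' prefix property). Uses the current RNG stream; seed with [set.seed()]
#' or the `seed` argument of [ir_fit()] for reproducibility.
#'
#' @param bounds An [ir_bounds()] object.
#' @param n_starts Number of starting points (`>= 1`).
#' @return Matrix `n_starts x 2n`; columns ordered `m0_1..n, t1_1..n`.
#' @export
sample_starts <- function(bounds, n_starts) {
  stopifnot(inherits(bounds, "ir_bounds"), n_starts >= 1)
  bv <- bounds_vectors(bounds)
  p <- length(bv$lower)
  t(vapply(seq_len(n_starts),
           function(i) runif(p, bv$lower, bv$upper),
           numeric(p)))
}

#' Quadratic trust-region model
#'
#' Second-order Taylor model of the objective around the current iterate:
#' `m(s) = f + g's + s'Hs/2`. `m(0)` equals the current objective, and the
#' model is exact for quadratic objectives with their exact Hessian.
#'
#' @param fval Objective value at the expansion point.
#' @param gradient Gradient vector at the expansion point.
#' @param hessian Hessian (or Gauss-Newton approximation) matrix.
#' @return A function of the step `s` returning the model value.
#' @export
tr_quadratic_model <- function(fval, gradient, hessian) {
  if (any(!is.finite(gradient)) || any(!is.finite(hessian)))
    abort("non-finite gradient or Hessian entries; solver aborted.")
  force(fval)
  function(s) fval + sum(gradient * s) + 0.5 * sum(s * (hessian %*% s))
}

#' Two-dimensional subspace trust-region step
#'
#' Minimizes the quadratic model over the intersection of the trust region
#' with the plane spanned by the negative gradient and the Newton
#' direction (`H v = -g`); when the Gauss-Newton Hessian is singular the
#' subspace degenerates to the gradient direction alone. The subproblem is
#' solved exactly in the reduced space, so the step is never worse in
#' model value than the optimal step along the negative gradient.
#'
#' @param gradient Gradient vector at the current iterate.
#' @param hessian Symmetric curvature matrix.
#' @param radius Trust-region radius (`> 0`).
#' @return Step vector with `||s|| <= radius`; zero when `gradient` is zero.
#' @export
tr_subproblem_2d <- function(gradient, hessian, radius) {
  stopifnot(radius > 0)
  if (any(!is.finite(gradient)) || any(!is.finite(hessian)))
    abort("non-finite gradient or Hessian entries; solver aborted.")
  trs_2d_step_cpp(gradient, as.matrix(hessian), radius)
}

#' Ratio of actual to predicted reduction
#'
#' @param f_current Objective at the current iterate.
#' @param f_trial Objective at the trial point.
#' @param predicted_reduction Model decrease `m(0) - m(s)`; must be
#'   positive for a meaningful ratio (a non-positive prediction rejects
#'   the step outright).
#' @return The ratio `rho`, or `-Inf` when the predicted reduction is not
#'   positive.
#' @export
tr_step_quality <- function(f_current, f_trial, predicted_reduction) {
  if (!is.finite(predicted_reduction) || predicted_reduction <= 0) return(-Inf)
  (f_current - f_trial) / predicted_reduction
}

#' Trust-region radius update and acceptance decision
#'
#' Improving steps are accepted; when the model agreement `rho` falls
#' below the low threshold the radius shrinks toward the attempted step
#' length, and a near-boundary step with agreement above the high
#' threshold grows the radius.
#'
#' @param control A [trf_control()] object.
#' @param rho Ratio of actual to predicted reduction.
#' @param step_norm Length of the attempted step (scaled coordinates).
#' @param radius Current radius.
#' @return List with `accepted` (logical) and `radius` (new radius).
#' @export
tr_update_radius <- function(control, rho, step_norm, radius) {
  accepted <- is.finite(rho) && rho > 0
  if (!accepted || rho < control$accept_threshold_low) {
    radius <- control$radius_shrink * min(radius, step_norm)
  } else if (rho > control$accept_threshold_high && step_norm >= 0.8 * radius) {
    radius <- control$radius_grow * radius
  }
  list(accepted = accepted, radius = radius)
}

#' Generic bound-constrained trust-region least squares
#'
#' Minimizes `sum(resid_fn(x)^2)` subject to box constraints with the same
#' trust-region-reflective iteration used for the inversion-recovery
#' model. Intended for cross-checks on standard test problems; the fast
#' compiled path for the relaxation model is [ir_fit()].
#'
#' @param resid_fn Function of `x` returning the residual vector.
#' @param jac_fn Function of `x` returning the Jacobian of the residuals.
#' @param x0 Starting point (projected strictly inside the bounds).
#' @param lower,upper Bound vectors (finite, `lower < upper`).
#' @param control A [trf_control()] object.
#' @return List with `x`, `objective`, `iterations`, `converged`,
#'   `status`, and `trace` (objective at accepted iterates).
#' @examples
#' rosen_r <- function(x) c(10 * (x[2] - x[1]^2), 1 - x[1])
#' rosen_j <- function(x) matrix(c(-20 * x[1], -1, 10, 0), 2, 2)
#' trf_minimize(rosen_r, rosen_j, c(-1.2, 1), c(-2, -2), c(2, 2))$x
#' @export
trf_minimize <- function(resid_fn, jac_fn, x0, lower, upper,
                         control = trf_control()) {
  stopifnot(inherits(control, "trf_control"))
  res <- trf_solve_fn_cpp(resid_fn, jac_fn, as.numeric(x0),
                          as.numeric(lower), as.numeric(upper),
                          unclass(control))
  if (identical(res$status, "objective not finite at starting point"))
    abort("objective is not finite at the starting point.")
  res
}

# Single-start compiled solve of the IR model; returns the raw solver
# record (x, objective, iterations, converged, status, trace).
ir_solve_one <- function(series, n_components, start, bounds,
                         control = trf_control()) {
  check_series(series, n_components)
  bv <- bounds_vectors(bounds)
  res <- trf_solve_ir_cpp(series$ti_ms, series$magnitude,
                          as.integer(n_components), as.numeric(start),
                          bv$lower, bv$upper, unclass(control))
  if (identical(res$status, "objective not finite at starting point"))
    abort("objective is not finite at the starting point.")
  res
}

#' Fit the multi-component relaxation model to a voxel series
#'
#' Multi-start bound-constrained trust-region nonlinear least squares: the
#' local solver is started from `n_starts` random points drawn uniformly
#' within the bounds (or from the rows of `starts`), and the local
#' solution of least objective wins. The multi-start restart is what lets
#' the fit escape the local nonoptimality traps of the multiexponential
#' objective; with a single start the solver is purely local.
#'
#' @param series Data frame with columns `ti_ms` (strictly increasing, ms)
#'   and `magnitude`. Must have at least `2 * n_components` rows.
#' @param n_components Number of `(M0, T1)` component pairs, 1 to 7.
#' @param bounds An [ir_bounds()] object; default derives M0 bounds from
#'   the series maximum and T1 bounds from literature extremes.
#' @param n_starts Number of random starting points (`>= 1`).
#' @param seed Optional integer seed for the start sampling; the caller's
#'   RNG state is preserved.
#' @param starts Optional matrix of starting points (`n_starts x 2n`,
#'   columns `m0_1..n, t1_1..n`) overriding random sampling.
#' @param control A [trf_control()] object.
#' @return An object of class `ir_fit`: the best-fit parameters are in
#'   `$params` (tibble with `component`, `m0`, `t1_ms`, sorted by T1) and
#'   per-start diagnostics in `$starts` (tibble with `start`, `objective`,
#'   `iterations`, `converged`, `status`). Use [tidy()] / [glance()] /
#'   [autoplot()] to inspect.
#' @examples
#' truth <- tibble::tibble(m0 = c(60, 40), t1_ms = c(700, 1400))
#' ti <- seq(50, 3000, length.out = 40)
#' series <- tibble::tibble(ti_ms = ti, magnitude = ir_signal(truth, ti))
#' fit <- ir_fit(series, n_components = 2, n_starts = 20, seed = 1)
#' tidy(fit)
#' @export
ir_fit <- function(series, n_components, bounds = NULL, n_starts = 100,
                   seed = NULL, starts = NULL, control = trf_control()) {
  n <- as.integer(n_components)
  check_series(series, n)
  if (n > 7) abort("the model supports at most 7 components per voxel.")
  if (is.null(bounds)) bounds <- ir_bounds(series, n)
  stopifnot(inherits(bounds, "ir_bounds"), inherits(control, "trf_control"))
  if (is.null(starts)) {
    if (n_starts < 1) abort("`n_starts` must be at least 1.")
    starts <- with_seed(seed, sample_starts(bounds, n_starts))
  } else {
    starts <- as.matrix(starts)
    if (ncol(starts) != 2 * n)
      abort(sprintf("`starts` must have %d columns (m0 then t1).", 2 * n))
  }
  bv <- bounds_vectors(bounds)
  res <- trf_multistart_ir_cpp(series$ti_ms, series$magnitude, n, starts,
                               bv$lower, bv$upper, unclass(control))
  if (res$best_index < 1) {
    abort(c("all starts failed to produce a finite objective.",
            paste("statuses:", paste(unique(res$statuses), collapse = "; "))))
  }
  x <- res$best_x
  ord <- order(x[n + seq_len(n)])
  params <- tibble(component = seq_len(n),
                   m0 = x[ord], t1_ms = x[n + ord])
  structure(list(params = params,
                 objective = res$best_objective,
                 mse = res$best_objective / nrow(series),
                 n_components = n,
                 best_start = res$best_index,
                 starts = tibble(start = seq_len(nrow(starts)),
                                 objective = res$objectives,
                                 iterations = res$iterations,
                                 converged = res$converged,
                                 status = res$statuses),
                 start_points = starts,
                 bounds = bounds,
                 control = control,
                 series = as_tibble(series),
                 seed = seed),
            class = "ir_fit")
}

#' @export
print.ir_fit <- function(x, ...) {
  cat(sprintf("Multi-component IR fit: %d component(s), %d start(s)\n",
              x$n_components, nrow(x$starts)))
  cat(sprintf("  objective (SSE): %.6g   MSE: %.6g   best start: %d\n",
              x$objective, x$mse, x$best_start))
  print(x$params)
  invisible(x)
}

#' @rdname ir_fit
#' @param x An `ir_fit` object.
#' @param ... Unused.
#' @method tidy ir_fit
#' @export
tidy.ir_fit <- function(x, ...) x$params

#' @rdname ir_fit
#' @method glance ir_fit
#' @export
glance.ir_fit <- function(x, ...) {
  tibble(objective = x$objective,
         mse = x$mse,
         n_components = x$n_components,
         n_points = nrow(x$series),
         n_starts = nrow(x$starts),
         n_converged = sum(x$starts$converged),
         best_start = x$best_start)
}
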