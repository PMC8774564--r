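#' Magnitude inversion-recovery signal of a single component
#'
#' Evaluates `m0 * |1 - 2 exp(-ti_ms / t1_ms)|`, the magnitude
#' inversion-recovery kernel of one tissue component under the assumptions
#' of a 180-degree inversion and a repetition time much longer than T1.
#' The kernel is zero at the component's null point `ti = t1 * log(2)` and
#' never exceeds `m0`.
#'
#' @param m0 Component magnetization at `TI = 0` (signal units, `>= 0`).
#' @param t1_ms Longitudinal relaxation time in milliseconds (`> 0`).
#' @param ti_ms Inversion time(s) in milliseconds (`>= 0`). Vectorized.
#' @return Numeric vector of signal magnitudes, in `[0, m0]`.
#' @examples
#' ir_component_signal(1, 700, 700 * log(2))  # null point: 0
#' ir_component_signal(5, 700, 0)             # |1 - 2| = 1: returns 5
#' @export
ir_component_signal <- function(m0, t1_ms, ti_ms) {
  if (any(!is.finite(t1_ms)) || any(t1_ms <= 0))
    abort("`t1_ms` must be positive and finite.")
  if (any(m0 < 0)) abort("`m0` must be non-negative.")
  if (any(ti_ms < 0)) abort("`ti_ms` must be non-negative.")
  m0 * abs(1 - 2 * exp(-ti_ms / t1_ms))
}

# Validate a component-parameter data frame (columns m0, t1_ms).
check_params <- function(params, arg = "params") {
  if (!is.data.frame(params) || !all(c("m0", "t1_ms") %in% names(params)))
    abort(sprintf("`%s` must be a data frame with columns `m0` and `t1_ms`.", arg))
  if (nrow(params) < 1) abort(sprintf("`%s` must have at least one component.", arg))
  if (nrow(params) > 7)
    abort("the model supports at most 7 components per voxel.")
  if (any(!is.finite(params$m0)) || any(params$m0 < 0))
    abort("all `m0` must be finite and non-negative.")
  if (any(!is.finite(params$t1_ms)) || any(params$t1_ms <= 0))
    abort("all `t1_ms` must be finite and positive.")
  invisible(params)
}

# Validate an inversion-recovery series data frame (columns ti_ms,
# magnitude); optionally enforce the identifiability floor of 2n points.
check_series <- function(series, n_components = NULL, arg = "series") {
  if (!is.data.frame(series) || !all(c("ti_ms", "magnitude") %in% names(series)))
    abort(sprintf("`%s` must be a data frame with columns `ti_ms` and `magnitude`.", arg))
  if (nrow(series) < 1) abort(sprintf("`%s` needs at least one point.", arg))
  if (any(!is.finite(series$ti_ms)) || any(series$ti_ms < 0))
    abort("`ti_ms` must be finite and non-negative.")
  if (any(diff(series$ti_ms) <= 0))
    abort("`ti_ms` must be strictly increasing.")
  if (any(!is.finite(series$magnitude)))
    abort("`magnitude` must be finite.")
  if (!is.null(n_components) && nrow(series) < 2 * n_components)
    abort(sprintf(
      "series has %d points but fitting %d components requires at least %d (two per free parameter).",
      nrow(series), n_components, 2 * n_components))
  invisible(series)
}

#' Multi-component forward signal
#'
#' Sums the magnitude inversion-recovery kernels of all components:
#' `M(TI) = sum_j m0_j |1 - 2 exp(-TI / t1_j)|`.
#'
#' @param params Data frame of component parameters with columns `m0` and
#'   `t1_ms`, one row per component (at most 7).
#' @param ti_ms Inversion time(s) in milliseconds. Vectorized.
#' @return Numeric vector of voxel magnitudes, same length as `ti_ms`.
#' @examples
#' params <- tibble::tibble(m0 = c(1, 1), t1_ms = c(700, 1400))
#' ir_signal(params, 700 * log(2))  # only the 1400 ms component contributes
#' @export
ir_signal <- function(params, ti_ms) {
  check_params(params)
  if (any(ti_ms < 0)) abort("`ti_ms` must be non-negative.")
  kern <- abs(1 - 2 * exp(-outer(as.numeric(ti_ms), params$t1_ms, "/")))
  as.vector(kern %*% params$m0)
}

#' Residuals of the multi-component model against a measured series
#'
#' @param series Data frame with columns `ti_ms` and `magnitude`.
#' @inheritParams ir_signal
#' @return Numeric vector `magnitude - ir_signal(params, ti_ms)`.
#' @export
ir_residuals <- function(series, params) {
  check_series(series)
  check_params(params)
  series$magnitude - ir_signal(params, series$ti_ms)
}

#' Sum-of-squares objective
#'
#' The nonlinear least-squares objective minimized by the solver: the sum
#' of squared residuals of the multi-component magnitude model. It is zero
#' exactly when the model reproduces the series.
#'
#' @inheritParams ir_residuals
#' @return Scalar `sum(ir_residuals(series, params)^2) >= 0`.
#' @export
ir_objective <- function(series, params) {
  sum(ir_residuals(series, params)^2)
}

#' Analytic Jacobian of the forward model
#'
#' Partial derivatives of the model magnitude at each inversion time with
#' respect to each parameter. The absolute value in the kernel is
#' non-differentiable where `1 - 2 exp(-TI/T1) = 0`; there the convention
#' `sign(0) = 0` (a valid subgradient) is used, so the T1 derivative
#' vanishes at a component's null point.
#'
#' @inheritParams ir_signal
#' @return Matrix of size `length(ti_ms) x 2n` with columns
#'   `m0_1, ..., m0_n, t1_1, ..., t1_n`.
#' @seealso [ir_gradient()] for the objective gradient `-2 J'r` and
#'   [ir_gn_hessian()] for the Gauss-Newton Hessian `2 J'J`.
#' @export
ir_jacobian <- function(params, ti_ms) {
  check_params(params)
  ti_ms <- as.numeric(ti_ms)
  n <- nrow(params)
  e <- exp(-outer(ti_ms, params$t1_ms, "/"))
  k <- 1 - 2 * e
  dm0 <- abs(k)
  dt1 <- sweep(sign(k) * (-2) * e * outer(ti_ms, params$t1_ms^2, "/"),
               2, params$m0, "*")
  J <- cbind(dm0, dt1)
  colnames(J) <- c(paste0("m0_", seq_len(n)), paste0("t1_", seq_len(n)))
  J
}

#' Gradient of the objective
#'
#' @inheritParams ir_residuals
#' @return Numeric vector of length `2n`: `-2 t(J) %*% r`.
#' @export
ir_gradient <- function(series, params) {
  r <- ir_residuals(series, params)
  J <- ir_jacobian(params, series$ti_ms)
  as.vector(-2 * crossprod(J, r))
}

#' Gauss-Newton Hessian of the objective
#'
#' The default curvature model used in the trust-region quadratic model:
#' `2 t(J) %*% J`, which drops the residual-curvature term of the exact
#' Hessian (standard for least squares).
#'
#' @inheritParams ir_signal
#' @return Symmetric `2n x 2n` matrix.
#' @export
ir_gn_hessian <- function(params, ti_ms) {
  J <- ir_jacobian(params, ti_ms)
  2 * crossprod(J)
}
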