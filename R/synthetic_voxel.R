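#' Linearly spaced inversion-time schedule
#'
#' @param n Number of inversion times (`>= 2`).
#' @param lo_ms,hi_ms Endpoints in milliseconds, both included.
#' @return Numeric vector of `n` equally spaced TI values.
#' @examples
#' ti_grid(3, 0, 100)       # 0, 50, 100
#' range(ti_grid(105, 50, 3000))
#' @export
ti_grid <- function(n, lo_ms, hi_ms) {
  if (n < 2) abort("`n` must be at least 2.")
  if (!(lo_ms < hi_ms)) abort("`lo_ms` must be below `hi_ms`.")
  seq(lo_ms, hi_ms, length.out = n)
}

#' Random component magnetizations with a representation floor
#'
#' Draws component fractions uniformly on the simplex subject to a
#' minimum representation per component, then scales them to `total_m0`:
#' `f = min_fraction + (1 - n * min_fraction) * Dirichlet(1, ..., 1)`.
#' Every fraction is at least `min_fraction` and the fractions sum to one.
#'
#' @param n_components Number of components.
#' @param min_fraction Representation floor per component (default 5%).
#' @param total_m0 Total magnetization the fractions are scaled to.
#' @return Numeric vector of `n_components` magnetizations summing to
#'   `total_m0`. Uses the current RNG stream.
#' @export
sample_m0_fractions <- function(n_components, min_fraction = 0.05,
                                total_m0 = 1) {
  n <- as.integer(n_components)
  if (n < 1) abort("`n_components` must be at least 1.")
  if (min_fraction * n > 1)
    abort(sprintf("min_fraction = %g is infeasible for %d components.",
                  min_fraction, n))
  g <- stats::rexp(n)
  f <- min_fraction + (1 - n * min_fraction) * g / sum(g)
  f * total_m0
}

#' Specification of the single-voxel simulation
#'
#' Describes the synthetic single-voxel study: seven components with fixed
#' literature-anchored T1 values, random M0 with a 5% representation
#' floor, 105 linearly spaced inversion times between 50 and 3000 ms, and
#' additive Gaussian magnitude noise over a fixed variance ladder. The M0
#' scale is calibrated so the noiseless series has mean squared signal
#' `signal_power`, which ties the noise variances to the reported
#' signal-to-noise ratios (e.g. variance 0.1 gives about 61 dB).
#'
#' @param t1_ms Ground-truth T1 values (ms), one per component.
#' @param n_ti Number of inversion times.
#' @param ti_range_ms Length-2 TI range in ms.
#' @param min_fraction Minimum M0 representation per component.
#' @param noise_variances Variance ladder for the Gaussian magnitude noise.
#' @param signal_power Target mean squared noiseless signal (signal
#'   units squared) used to calibrate the M0 scale; set to `NULL` and
#'   supply `total_m0` to fix the scale directly.
#' @param total_m0 Explicit total magnetization (used when
#'   `signal_power` is `NULL`).
#' @return A list of class `voxel_sim_spec`.
#' @export
voxel_sim_spec <- function(t1_ms = c(700, 800, 1100, 1200, 1500, 1700, 2000),
                           n_ti = 105L,
                           ti_range_ms = c(50, 3000),
                           min_fraction = 0.05,
                           noise_variances = c(0, 0.1, 1, 5, 10, 25, 50, 100),
                           signal_power = 1.26e5,
                           total_m0 = NULL) {
  if (any(t1_ms <= 0)) abort("`t1_ms` must be positive.")
  if (length(t1_ms) > 7) abort("at most 7 components are supported.")
  if (min_fraction * length(t1_ms) > 1) abort("`min_fraction` infeasible.")
  if (any(noise_variances < 0)) abort("noise variances must be >= 0.")
  if (is.null(signal_power) && is.null(total_m0))
    abort("one of `signal_power` or `total_m0` must be given.")
  structure(list(t1_ms = as.numeric(t1_ms),
                 n_components = length(t1_ms),
                 n_ti = as.integer(n_ti),
                 ti_range_ms = ti_range_ms,
                 min_fraction = min_fraction,
                 noise_variances = noise_variances,
                 signal_power = signal_power,
                 total_m0 = total_m0),
            class = "voxel_sim_spec")
}

#' Simulate a single-voxel inversion-recovery series
#'
#' Draws random ground-truth magnetizations, evaluates the noiseless
#' multi-component magnitude signal on the TI grid, and adds independent
#' Gaussian noise of the requested variance to each point. Magnitudes are
#' deliberately not clamped at zero after noise addition, mirroring
#' direct Gaussian corruption of magnitude data.
#'
#' @param spec A [voxel_sim_spec()].
#' @param variance Gaussian noise variance (0 reproduces the forward
#'   model exactly).
#' @param seed Optional integer seed (caller's RNG preserved).
#' @param truth Optional data frame (`m0`, `t1_ms`) to reuse a previous
#'   ground truth and add fresh noise to the same underlying signal.
#' @return A list of class `ir_voxel_sim` with `$series` (tibble `ti_ms`,
#'   `magnitude`), `$truth` (tibble `m0`, `t1_ms`), `$noiseless`,
#'   `$variance`, `$snr_db`, `$seed`.
#' @export
simulate_voxel_series <- function(spec = voxel_sim_spec(), variance = 0,
                                  seed = NULL, truth = NULL) {
  stopifnot(inherits(spec, "voxel_sim_spec"))
  if (variance < 0) abort("`variance` must be >= 0.")
  ti <- ti_grid(spec$n_ti, spec$ti_range_ms[1], spec$ti_range_ms[2])
  with_seed(seed, {
    if (is.null(truth)) {
      m0 <- sample_m0_fractions(spec$n_components, spec$min_fraction,
                                spec$total_m0 %||% 1)
      truth <- tibble(m0 = m0, t1_ms = spec$t1_ms)
      if (!is.null(spec$signal_power)) {
        # calibrate the M0 scale to the target noiseless signal power
        p1 <- mean(ir_signal(truth, ti)^2)
        truth$m0 <- truth$m0 * sqrt(spec$signal_power / p1)
      }
    } else {
      check_params(truth)
    }
    noiseless <- ir_signal(truth, ti)
    magnitude <- noiseless +
      if (variance > 0) rnorm(length(ti), 0, sqrt(variance)) else 0
    structure(list(series = tibble(ti_ms = ti, magnitude = magnitude),
                   truth = as_tibble(truth),
                   noiseless = noiseless,
                   variance = variance,
                   snr_db = compute_snr_db(noiseless, variance),
                   seed = seed),
              class = "ir_voxel_sim")
  })
}

#' Signal-to-noise ratio in decibels
#'
#' `10 log10(mean(noiseless^2) / variance)`; infinite for zero variance.
#'
#' @param noiseless Noiseless magnitude vector, or a series data frame
#'   with a `magnitude` column.
#' @param variance Gaussian noise variance (`>= 0`).
#' @return SNR in dB (`Inf` when `variance == 0`).
#' @examples
#' compute_snr_db(rep(10, 5), 1)  # 20 dB
#' @export
compute_snr_db <- function(noiseless, variance) {
  if (is.data.frame(noiseless)) noiseless <- noiseless$magnitude
  if (variance < 0) abort("`variance` must be >= 0.")
  if (variance == 0) return(Inf)
  10 * log10(mean(noiseless^2) / variance)
}

#' Write / read a simulated voxel dataset
#'
#' The series goes to `series.csv` (columns `TI_ms`, `magnitude`) and the
#' ground truth, noise variance and seed to `truth.json`.
#'
#' @param sim An `ir_voxel_sim` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_voxel_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "ir_voxel_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(data.frame(TI_ms = sim$series$ti_ms,
                       magnitude = sim$series$magnitude),
            file.path(dir, "series.csv"), row.names = FALSE)
  jsonlite::write_json(list(truth = as.list(sim$truth),
                            variance = sim$variance,
                            snr_db = sim$snr_db,
                            seed = sim$seed),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_voxel_dataset
#' @param path Path to a `series.csv` written by [write_voxel_dataset()]
#'   (or any CSV with columns `TI_ms`/`ti_ms` and `magnitude`).
#' @return For `read_voxel_series()`, a series tibble.
#' @export
read_voxel_series <- function(path) {
  df <- read.csv(path)
  names(df) <- tolower(names(df))
  if (!all(c("ti_ms", "magnitude") %in% names(df)))
    abort("CSV must have columns `TI_ms` and `magnitude`.")
  check_series(df[c("ti_ms", "magnitude")])
  as_tibble(df[c("ti_ms", "magnitude")])
}
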