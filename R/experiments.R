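#' Starting-point experiment: error versus number of starts
#'
#' Repeats the noiseless seven-component single-voxel simulation, fits
#' each repetition once per entry of `n_starts`, matches components, and
#' collects per-coefficient relative errors and per-repetition MSE. With
#' many starts the noiseless model is recovered essentially exactly; a
#' single start routinely terminates in a local nonoptimality trap.
#'
#' @param spec A [voxel_sim_spec()] describing the simulation.
#' @param n_starts Integer vector of start counts to compare.
#' @param n_repetitions Number of independent simulate-and-fit repetitions.
#' @param seed Master seed; repetition data and start sampling use
#'   sub-seeds derived from it.
#' @param control A [trf_control()] object.
#' @return A list of class `ir_experiment` with `$errors` (tibble:
#'   `n_starts`, `repetition`, `family`, `component`, `truth`, `estimate`,
#'   `rel_error_pct`), `$fits` (tibble: `n_starts`, `repetition`, `mse`,
#'   `objective`), and `$summary` (min/mean/max by `n_starts` and family).
#' @export
run_start_count_experiment <- function(spec = voxel_sim_spec(),
                                       n_starts = c(1L, 100L),
                                       n_repetitions = 10L,
                                       seed = 1L,
                                       control = trf_control()) {
  seeds <- derive_seeds(seed, 2L * n_repetitions * length(n_starts))
  si <- 0L
  rows <- list()
  fit_rows <- list()
  for (rep_i in seq_len(n_repetitions)) {
    si <- si + 1L
    sim <- simulate_voxel_series(spec, variance = 0, seed = seeds[si])
    # no representation prior in the noiseless experiment: M0 is bounded
    # below by zero and above by the data maximum (the 5% floor belongs
    # to the noise sweep, where it is the only prior assumed)
    bounds <- ir_bounds(sim$series, spec$n_components, m0_lower = 0)
    for (ns in n_starts) {
      si <- si + 1L
      fit <- ir_fit(sim$series, spec$n_components, bounds = bounds,
                    n_starts = ns, seed = seeds[si], control = control)
      err <- component_errors(fit, sim$truth)
      rows[[length(rows) + 1L]] <-
        dplyr::mutate(err, n_starts = ns, repetition = rep_i,
                      .before = 1)
      fit_rows[[length(fit_rows) + 1L]] <-
        tibble(n_starts = ns, repetition = rep_i,
               mse = fit$mse, objective = fit$objective)
    }
  }
  errors <- dplyr::bind_rows(rows)
  structure(list(errors = errors,
                 fits = dplyr::bind_rows(fit_rows),
                 summary = error_summary(errors, .data$n_starts),
                 spec = spec, seed = seed),
            class = "ir_experiment")
}

#' Noise-sweep experiment: error versus noise variance / SNR
#'
#' For each repetition a fresh noiseless seven-component ground truth is
#' drawn; for each noise variance, Gaussian noise is added to that same
#' underlying signal, the model is refitted with no prior knowledge of
#' the parameters (literature T1 bounds, M0 bounded by the data maximum
#' with a 5% representation floor), components are matched, and relative
#' errors are recorded together with the series SNR.
#'
#' @inheritParams run_start_count_experiment
#' @param variances Noise variances to sweep (defaults to the spec's
#'   ladder).
#' @param n_starts Starts per fit.
#' @return A list of class `ir_experiment` with `$errors` (tibble:
#'   `variance`, `snr_db`, `repetition`, `family`, `component`, `truth`,
#'   `estimate`, `rel_error_pct`), `$fits`, and `$summary` (by variance
#'   and family, averaged over repetitions).
#' @export
run_noise_sweep <- function(spec = voxel_sim_spec(),
                            variances = NULL,
                            n_starts = 100L,
                            n_repetitions = 1L,
                            seed = 1L,
                            control = trf_control()) {
  variances <- variances %||% spec$noise_variances
  seeds <- derive_seeds(seed, n_repetitions * (1L + 2L * length(variances)))
  si <- 0L
  rows <- list()
  fit_rows <- list()
  for (rep_i in seq_len(n_repetitions)) {
    si <- si + 1L
    base <- simulate_voxel_series(spec, variance = 0, seed = seeds[si])
    for (v in variances) {
      si <- si + 2L
      sim <- simulate_voxel_series(spec, variance = v, seed = seeds[si - 1L],
                                   truth = base$truth)
      bounds <- ir_bounds(sim$series, spec$n_components)
      fit <- ir_fit(sim$series, spec$n_components, bounds = bounds,
                    n_starts = n_starts, seed = seeds[si], control = control)
      err <- component_errors(fit, sim$truth)
      rows[[length(rows) + 1L]] <-
        dplyr::mutate(err, variance = v, snr_db = sim$snr_db,
                      repetition = rep_i, .before = 1)
      fit_rows[[length(fit_rows) + 1L]] <-
        tibble(variance = v, snr_db = sim$snr_db, repetition = rep_i,
               mse = fit$mse, objective = fit$objective)
    }
  }
  errors <- dplyr::bind_rows(rows)
  structure(list(errors = errors,
                 fits = dplyr::bind_rows(fit_rows),
                 summary = error_summary(errors, .data$variance, .data$snr_db),
                 spec = spec, seed = seed),
            class = "ir_experiment")
}

#' Phantom experiment: voxelwise two-component fit of the simulated series
#'
#' Simulates the two-pool phantom image series, fits the two-component
#' model independently to every fully covered object voxel (bounds as in
#' the noise sweep: literature T1 range, M0 bounded by the voxel's data
#' maximum), matches components per voxel by T1, and reports per-pool
#' relative T1 errors plus the pooled T1 estimates for histogramming.
#' M0 errors are not reported: the fitted amplitudes absorb the unknown
#' T2 weighting, so they have no direct counterpart in the pool densities.
#'
#' @param spec A [phantom_spec()]. The default experiment condition adds
#'   mild Rician noise (complex-channel sd 0.5% of the amplitude scale).
#' @param n_starts Starts per voxel fit.
#' @param seed Master seed; each voxel derives an order-independent
#'   sub-seed from it.
#' @param control A [trf_control()] object.
#' @param max_voxels Optional cap on the number of object voxels fitted
#'   (subsampled deterministically); `NULL` fits all.
#' @return A list of class `ir_phantom_experiment` with `$estimates`
#'   (tibble: voxel coordinates, `pool`, `t1_true`, `t1_est`, `m0_est`,
#'   `rel_error_pct`, `objective`, `converged`), `$summary` (per-pool
#'   min/mean/max relative T1 error), `$t1_pooled` (all matched T1
#'   estimates), and the phantom itself in `$phantom`.
#' @export
run_phantom_experiment <- function(spec = NULL,
                                   n_starts = 25L,
                                   seed = 1L,
                                   control = trf_control(),
                                   max_voxels = NULL) {
  if (is.null(spec))
    spec <- phantom_spec(noise_mode = "rician", noise_sd = 0.5)
  seeds <- derive_seeds(seed, 2L)
  phantom <- simulate_phantom(spec, seed = seeds[1])
  vol <- as_volume_series(phantom)
  maps <- fit_volume(vol, n_components = nrow(spec$pools),
                     n_starts = n_starts, seed = seeds[2],
                     control = control, max_voxels = max_voxels)
  est <- tidy(maps)
  truth_pools <- spec$pools

  # per voxel, match fitted components to pool T1s
  est_split <- split(est, interaction(est$x, est$y, est$z, drop = TRUE))
  rows <- lapply(est_split, function(df) {
    matched <- match_components(
      tibble(m0 = df$m0, t1_ms = df$t1_ms),
      tibble(m0 = truth_pools$density, t1_ms = truth_pools$t1_ms))
    tibble(x = df$x[1], y = df$y[1], z = df$z[1],
           pool = seq_len(nrow(truth_pools)),
           t1_true = truth_pools$t1_ms,
           t1_est = matched$t1_ms,
           m0_est = matched$m0,
           rel_error_pct = relative_error_pct(matched$t1_ms,
                                              truth_pools$t1_ms),
           objective = df$objective[1],
           converged = df$converged[1])
  })
  estimates <- dplyr::bind_rows(rows)
  ok <- estimates[estimates$converged & is.finite(estimates$t1_est), ]
  summary <- ok |>
    dplyr::group_by(pool = .data$pool, t1_true = .data$t1_true) |>
    dplyr::summarise(n_voxels = dplyr::n(),
                     min_error_pct = min(.data$rel_error_pct),
                     mean_error_pct = mean(.data$rel_error_pct),
                     max_error_pct = max(.data$rel_error_pct),
                     .groups = "drop")
  structure(list(estimates = estimates,
                 summary = summary,
                 t1_pooled = ok$t1_est,
                 n_failed = sum(!estimates$converged) / nrow(truth_pools),
                 phantom = phantom,
                 maps = maps,
                 n_starts = n_starts, seed = seed),
            class = "ir_phantom_experiment")
}

#' Write an experiment's tables to disk
#'
#' Emits `summary.csv` (the table-style min/mean/max layout),
#' `errors.csv` (the long per-coefficient table) and `provenance.json`
#' (seed and configuration) into `dir`.
#'
#' @param experiment An `ir_experiment` or `ir_phantom_experiment`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- if (!is.null(experiment$errors)) experiment$errors else experiment$estimates
  write.csv(long, file.path(dir, "errors.csv"), row.names = FALSE)
  write.csv(experiment$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  prov <- list(seed = experiment$seed,
               class = class(experiment),
               spec = if (!is.null(experiment$spec))
                 unclass(experiment$spec)[!vapply(unclass(experiment$spec), is.data.frame, TRUE)]
               else NULL)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(dir)
}
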