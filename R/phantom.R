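#' Specification of the two-pool imaging phantom
#'
#' Describes a cylindrical (disc-per-slice) virtual object in which every
#' voxel mixes two relaxation pools, imaged by an idealized
#' inversion-recovery sequence: per voxel and inversion time the signal is
#' `amplitude * sum_p density_p * exp(-te/t2_p) * |1 - 2 exp(-ti/t1_p)|`,
#' i.e. the T2 decay at the echo time is folded into an effective pool
#' amplitude and k-space traversal is not modeled. Optionally the object
#' is defined on a finer grid (e.g. 100 x 100) and area-resampled onto
#' the acquisition matrix, creating partial-volume edge voxels.
#'
#' @param matrix_size Acquired in-plane matrix (pixels per side).
#' @param n_slices Number of (identical) slices.
#' @param object_radius Disc radius in acquisition pixels.
#' @param pools Data frame with columns `t1_ms`, `t2_ms`, `density`
#'   (densities summing to 1), one row per pool.
#' @param n_ti,ti_range_ms Inversion-time schedule (linear, inclusive).
#' @param te_ms,tr_ms Echo and repetition time in ms (TR only documents
#'   the long-TR assumption; it does not enter the signal).
#' @param amplitude Overall signal scale (signal units).
#' @param noise_mode `"none"` or `"rician"` (independent Gaussian noise
#'   on the real and imaginary channel before the magnitude).
#' @param noise_sd Standard deviation of each complex channel (signal
#'   units) when `noise_mode = "rician"`.
#' @param object_grid_size Optional finer object grid per side (e.g. 100)
#'   rendered then area-resampled to `matrix_size`; `NULL` renders the
#'   disc directly on the acquisition grid.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(matrix_size = 64L, n_slices = 1L,
                         object_radius = 24,
                         pools = tibble(t1_ms = c(700, 800),
                                        t2_ms = c(80, 90),
                                        density = c(0.4, 0.6)),
                         n_ti = 70L, ti_range_ms = c(50, 960),
                         te_ms = 30, tr_ms = 10000,
                         amplitude = 100,
                         noise_mode = c("none", "rician"),
                         noise_sd = 0,
                         object_grid_size = NULL) {
  noise_mode <- match.arg(noise_mode)
  if (!all(c("t1_ms", "t2_ms", "density") %in% names(pools)))
    abort("`pools` needs columns `t1_ms`, `t2_ms`, `density`.")
  if (abs(sum(pools$density) - 1) > 1e-9)
    abort("pool densities must sum to 1.")
  if (n_ti < 2) abort("`n_ti` must be at least 2.")
  if (matrix_size < 4 || object_radius <= 0 || object_radius > matrix_size / 2)
    abort("invalid phantom geometry.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  structure(list(matrix_size = as.integer(matrix_size),
                 n_slices = as.integer(n_slices),
                 object_radius = object_radius,
                 pools = as_tibble(pools),
                 n_ti = as.integer(n_ti),
                 ti_range_ms = ti_range_ms,
                 te_ms = te_ms, tr_ms = tr_ms,
                 amplitude = amplitude,
                 noise_mode = noise_mode,
                 noise_sd = noise_sd,
                 object_grid_size = object_grid_size),
            class = "phantom_spec")
}

# Fractional object coverage of each acquisition pixel (disc object).
phantom_coverage <- function(spec) {
  ms <- spec$matrix_size
  centre <- (ms + 1) / 2
  if (is.null(spec$object_grid_size)) {
    xy <- expand.grid(x = seq_len(ms), y = seq_len(ms))
    cov <- as.numeric((xy$x - centre)^2 + (xy$y - centre)^2 <=
                        spec$object_radius^2)
  } else {
    # render on the finer object grid, then area-average per pixel
    og <- spec$object_grid_size
    sub <- 4L
    scale <- og / ms
    r_obj <- spec$object_radius * scale
    c_obj <- (og + 1) / 2
    offs <- (seq_len(sub) - 0.5) / sub
    cov <- matrix(0, ms, ms)
    for (ox in offs) for (oy in offs) {
      gx <- ((seq_len(ms) - 1) + ox) * scale + 0.5
      gy <- ((seq_len(ms) - 1) + oy) * scale + 0.5
      cov <- cov + outer(gx, gy, function(a, b)
        (a - c_obj)^2 + (b - c_obj)^2 <= r_obj^2)
    }
    cov <- as.numeric(cov / sub^2)
  }
  matrix(cov, ms, ms)
}

#' Simulate the two-pool phantom image series
#'
#' Generates one 3D magnitude volume per inversion time from the
#' signal-level phantom model, with optional Rician magnitude noise
#' (independent Gaussian noise added to the real and imaginary channel
#' before taking the modulus). Every voxel's ground-truth composition is
#' returned alongside.
#'
#' @param spec A [phantom_spec()].
#' @param seed Optional integer seed (caller's RNG preserved); only the
#'   noise consumes random numbers.
#' @return A list of class `ir_phantom`: `data` (4D array x, y, z, TI),
#'   `ti_ms`, `mask` (3D logical, fully covered object voxels), `truth`
#'   (tibble with `x`, `y`, `z`, `pool`, `density`, `t1_ms`, `t2_ms` for
#'   in-object voxels), `spec`, `seed`.
#' @export
simulate_phantom <- function(spec = phantom_spec(), seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  ms <- spec$matrix_size
  nz <- spec$n_slices
  ti <- ti_grid(spec$n_ti, spec$ti_range_ms[1], spec$ti_range_ms[2])
  cov <- phantom_coverage(spec)

  # effective pool amplitudes fold the TE-weighting into the density
  amp <- spec$amplitude * spec$pools$density * exp(-spec$te_ms / spec$pools$t2_ms)
  kern <- abs(1 - 2 * exp(-outer(ti, spec$pools$t1_ms, "/")))  # n_ti x pools
  curve <- as.vector(kern %*% amp)                              # per unit coverage

  plane <- as.vector(cov)                                       # ms*ms
  slice_series <- outer(plane, curve)                           # vox x ti
  data <- array(slice_series[rep(seq_along(plane), nz), ],
                dim = c(ms, ms, nz, spec$n_ti))

  with_seed(seed, {
    if (spec$noise_mode == "rician" && spec$noise_sd > 0) {
      nre <- array(rnorm(length(data), 0, spec$noise_sd), dim = dim(data))
      nim <- array(rnorm(length(data), 0, spec$noise_sd), dim = dim(data))
      data <- sqrt((data + nre)^2 + nim^2)
    }
    mask <- array(rep(plane >= 1 - 1e-9, nz), dim = c(ms, ms, nz))
    idx <- which(array(rep(plane > 0, nz), dim = c(ms, ms, nz)), arr.ind = TRUE)
    truth <- tidyr::crossing(tibble(x = idx[, 1], y = idx[, 2], z = idx[, 3]),
                             tibble(pool = seq_len(nrow(spec$pools))))
    truth <- dplyr::mutate(truth,
                           coverage = plane[.data$x + (.data$y - 1) * ms],
                           density = spec$pools$density[.data$pool] * .data$coverage,
                           t1_ms = spec$pools$t1_ms[.data$pool],
                           t2_ms = spec$pools$t2_ms[.data$pool])
    structure(list(data = data, ti_ms = ti, mask = mask, coverage = cov,
                   truth = truth, spec = spec, seed = seed),
              class = "ir_phantom")
  })
}

#' Write a phantom series to disk
#'
#' Writes the 4D magnitude stack as NIfTI (`phantom.nii.gz`), the TI
#' schedule as plain text (one ms value per line, `ti_ms.txt`), the
#' ground truth as CSV (`truth.csv`) and a provenance JSON.
#'
#' @param phantom An `ir_phantom` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "ir_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img <- RNifti::asNifti(phantom$data, pixdim = c(3, 3, 3, 1))
  RNifti::writeNifti(img, file.path(dir, "phantom.nii.gz"))
  writeLines(format(phantom$ti_ms, digits = 17, scientific = FALSE, trim = TRUE),
             file.path(dir, "ti_ms.txt"))
  write.csv(phantom$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  mask_img <- RNifti::asNifti(array(as.integer(phantom$mask),
                                    dim = dim(phantom$mask)),
                              pixdim = c(3, 3, 3))
  RNifti::writeNifti(mask_img, file.path(dir, "mask.nii.gz"))
  sp <- phantom$spec
  jsonlite::write_json(list(spec = sp[setdiff(names(sp), "pools")],
                            pools = sp$pools, seed = phantom$seed),
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
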