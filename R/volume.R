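#' Read a 4D inversion-recovery volume series
#'
#' Loads a 4D NIfTI magnitude series (x, y, z, TI), its sidecar TI
#' schedule (plain text, one ms value per line) and an optional 3D mask.
#' The schedule length must match the fourth dimension.
#'
#' @param image_path Path to the 4D NIfTI image.
#' @param ti_path Path to the TI schedule text file.
#' @param mask_path Optional path to a 3D NIfTI mask (nonzero = fit);
#'   `NULL` fits every voxel.
#' @return A list of class `ir_volume_series`: `data` (4D array),
#'   `ti_ms`, `mask` (3D logical), `reference` (the NIfTI image carrying
#'   the spatial metadata).
#' @export
read_volume_series <- function(image_path, ti_path, mask_path = NULL) {
  img <- RNifti::readNifti(image_path)
  data <- array(as.numeric(img), dim = dim(img))
  if (length(dim(data)) != 4)
    abort(sprintf("expected a 4D image, got %d dimension(s).",
                  length(dim(data))))
  ti <- as.numeric(readLines(ti_path))
  if (any(is.na(ti))) abort("TI schedule contains non-numeric lines.")
  if (length(ti) != dim(data)[4])
    abort(sprintf(
      "TI schedule has %d entries but the image has %d volumes.",
      length(ti), dim(data)[4]))
  mask <- if (is.null(mask_path)) {
    array(TRUE, dim = dim(data)[1:3])
  } else {
    m <- RNifti::readNifti(mask_path)
    dm <- c(dim(m), 1, 1)[1:3]  # trailing singleton dims may be dropped
    if (!all(dm == dim(data)[1:3]))
      abort(sprintf("mask dimensions (%s) do not match the image (%s).",
                    paste(dm, collapse = "x"),
                    paste(dim(data)[1:3], collapse = "x")))
    array(as.numeric(m) != 0, dim = dim(data)[1:3])
  }
  new_volume_series(data, ti, mask, reference = img)
}

new_volume_series <- function(data, ti_ms, mask, reference = NULL) {
  if (length(ti_ms) != dim(data)[4])
    abort("TI schedule length must match the fourth dimension.")
  if (any(diff(ti_ms) <= 0)) abort("`ti_ms` must be strictly increasing.")
  structure(list(data = data, ti_ms = as.numeric(ti_ms), mask = mask,
                 reference = reference),
            class = "ir_volume_series")
}

#' Convert a simulated phantom to a volume series
#'
#' @param phantom An `ir_phantom` from [simulate_phantom()].
#' @return An `ir_volume_series` whose mask is the phantom's fully
#'   covered object region.
#' @export
as_volume_series <- function(phantom) {
  stopifnot(inherits(phantom, "ir_phantom"))
  new_volume_series(phantom$data, phantom$ti_ms, phantom$mask)
}

#' Voxelwise multi-component fit of a volume series
#'
#' Applies the multi-start bound-constrained fit independently to every
#' masked voxel. Each voxel draws its starting points from a sub-seed
#' derived from the master seed and the voxel's flat index, so results
#' are identical regardless of traversal order. Per-voxel failures are
#' recorded in the convergence map and never abort the volume.
#'
#' @param volume An `ir_volume_series`.
#' @param n_components Components per voxel (1 to 7).
#' @param bounds Optional [ir_bounds()]; by default T1 spans the
#'   literature range and M0 is bounded per voxel by that voxel's maximum
#'   magnitude (with the 5% representation floor).
#' @param n_starts Starts per voxel.
#' @param seed Master seed for the per-voxel substreams.
#' @param control A [trf_control()] object.
#' @param max_voxels Optional deterministic cap on the number of masked
#'   voxels fitted (evenly spaced subsample); `NULL` fits all.
#' @return A list of class `ir_component_maps`: 4D arrays `m0` and
#'   `t1_ms` (x, y, z, component; components sorted by T1), 3D arrays
#'   `objective`, `converged`, `n_iter`. Unfitted voxels hold `NA`.
#' @export
fit_volume <- function(volume, n_components = 2L, bounds = NULL,
                       n_starts = 25L, seed = 1L,
                       control = trf_control(), max_voxels = NULL) {
  stopifnot(inherits(volume, "ir_volume_series"))
  n <- as.integer(n_components)
  if (n < 1 || n > 7) abort("`n_components` must be between 1 and 7.")
  if (length(volume$ti_ms) < 2 * n)
    abort(sprintf("schedule of length %d cannot identify %d components.",
                  length(volume$ti_ms), n))
  dims <- dim(volume$data)[1:3]
  nvox <- prod(dims)
  flat <- matrix(volume$data, nrow = nvox)
  idx_all <- which(as.vector(volume$mask))
  if (!is.null(max_voxels) && length(idx_all) > max_voxels)
    idx_all <- idx_all[unique(round(seq(1, length(idx_all),
                                        length.out = max_voxels)))]

  m0_map <- array(NA_real_, dim = c(dims, n))
  t1_map <- array(NA_real_, dim = c(dims, n))
  obj_map <- array(NA_real_, dim = dims)
  conv_map <- array(NA, dim = dims)
  iter_map <- array(NA_integer_, dim = dims)

  ctrl <- unclass(control)
  for (v in idx_all) {
    y <- flat[v, ]
    b <- bounds %||% ir_bounds(tibble(ti_ms = volume$ti_ms, magnitude = y), n)
    bv <- bounds_vectors(b)
    starts <- with_seed(voxel_seed(seed, v), sample_starts(b, n_starts))
    res <- trf_multistart_ir_cpp(volume$ti_ms, y, n, starts,
                                 bv$lower, bv$upper, ctrl)
    ijk <- arrayInd(v, dims)
    if (res$best_index >= 1) {
      x <- res$best_x
      ord <- order(x[n + seq_len(n)])
      m0_map[ijk[1], ijk[2], ijk[3], ] <- x[ord]
      t1_map[ijk[1], ijk[2], ijk[3], ] <- x[n + ord]
      obj_map[ijk[1], ijk[2], ijk[3]] <- res$best_objective
      conv_map[ijk[1], ijk[2], ijk[3]] <- any(res$converged)
      iter_map[ijk[1], ijk[2], ijk[3]] <- sum(res$iterations)
    } else {
      conv_map[ijk[1], ijk[2], ijk[3]] <- FALSE
    }
  }
  structure(list(m0 = m0_map, t1_ms = t1_map, objective = obj_map,
                 converged = conv_map, n_iter = iter_map,
                 ti_ms = volume$ti_ms, n_components = n,
                 n_starts = n_starts, seed = seed,
                 reference = volume$reference),
            class = "ir_component_maps")
}

#' @export
print.ir_component_maps <- function(x, ...) {
  fitted <- sum(!is.na(x$objective))
  cat(sprintf("Component maps: %d component(s), %d fitted voxel(s), %d starts, seed %s\n",
              x$n_components, fitted, x$n_starts, format(x$seed)))
  invisible(x)
}

#' Tidy per-voxel component estimates
#'
#' @param x An `ir_component_maps` object.
#' @param ... Unused.
#' @return Tibble with one row per fitted voxel and component: `x`, `y`,
#'   `z`, `component`, `m0`, `t1_ms`, `objective`, `converged`.
#' @method tidy ir_component_maps
#' @export
tidy.ir_component_maps <- function(x, ...) {
  dims <- dim(x$objective)
  fitted <- which(!is.na(x$objective))
  if (length(fitted) == 0) return(tibble())
  ijk <- arrayInd(fitted, dims)
  n <- x$n_components
  purrr::map_dfr(seq_len(n), function(comp) {
    sel <- cbind(ijk, comp)
    m0_v <- x$m0[sel]
    t1_v <- x$t1_ms[sel]
    obj_v <- x$objective[ijk]
    conv_v <- x$converged[ijk]
    tibble(x = ijk[, 1], y = ijk[, 2], z = ijk[, 3], component = comp,
           m0 = m0_v, t1_ms = t1_v, objective = obj_v, converged = conv_v)
  }) |> dplyr::arrange(.data$x, .data$y, .data$z, .data$component)
}

#' Write component maps as NIfTI volumes
#'
#' Writes `m0.nii.gz` and `t1_ms.nii.gz` (4D: x, y, z, component) plus
#' `objective.nii.gz`, `converged.nii.gz` and `provenance.json`. Spatial
#' metadata is copied from the input series when available.
#'
#' @param maps An `ir_component_maps` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_component_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "ir_component_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  as_img <- function(arr) {
    if (!is.null(maps$reference))
      RNifti::asNifti(arr, reference = maps$reference)
    else RNifti::asNifti(arr)
  }
  RNifti::writeNifti(as_img(maps$m0), file.path(dir, "m0.nii.gz"))
  RNifti::writeNifti(as_img(maps$t1_ms), file.path(dir, "t1_ms.nii.gz"))
  RNifti::writeNifti(as_img(maps$objective), file.path(dir, "objective.nii.gz"))
  RNifti::writeNifti(as_img(array(as.numeric(maps$converged),
                                  dim = dim(maps$converged))),
                     file.path(dir, "converged.nii.gz"))
  jsonlite::write_json(list(n_components = maps$n_components,
                            n_starts = maps$n_starts, seed = maps$seed,
                            ti_ms = maps$ti_ms),
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
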