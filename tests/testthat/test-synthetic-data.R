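test_that("TI grid is linear, endpoint-inclusive, and validated", {
  expect_equal(ti_grid(3, 0, 100), c(0, 50, 100))
  g <- ti_grid(105, 50, 3000)
  expect_length(g, 105)
  expect_equal(g[1], 50)
  expect_equal(g[105], 3000)
  expect_lt(diff(range(diff(g))), 1e-9)  # equal spacing
  expect_error(ti_grid(1, 0, 100), "at least 2")
  expect_error(ti_grid(10, 100, 100), "below")
})

test_that("M0 fractions respect the floor, the total, and the seed", {
  set.seed(1)
  for (i in 1:20) {
    m0 <- sample_m0_fractions(7, 0.05, total_m0 = 350)
    expect_true(all(m0 >= 0.05 * 350 - 1e-9))
    expect_equal(sum(m0), 350, tolerance = 1e-9)
  }
  a <- with(list(), { set.seed(5); sample_m0_fractions(7) })
  b <- with(list(), { set.seed(5); sample_m0_fractions(7) })
  expect_identical(a, b)
  expect_error(sample_m0_fractions(7, min_fraction = 0.2), "infeasible")
})

test_that("noiseless voxel simulation reproduces the forward model exactly", {
  spec <- voxel_sim_spec()
  sim <- simulate_voxel_series(spec, variance = 0, seed = 99)
  expect_equal(nrow(sim$series), 105)
  expect_equal(sim$series$magnitude, ir_signal(sim$truth, sim$series$ti_ms))
  expect_equal(ir_objective(sim$series, sim$truth), 0)
  # M0 scale calibration: noiseless power matches the target exactly
  expect_equal(mean(sim$noiseless^2), spec$signal_power, tolerance = 1e-9)
  # reproducibility
  sim2 <- simulate_voxel_series(spec, variance = 0, seed = 99)
  expect_identical(sim$series, sim2$series)
})

test_that("added noise follows the requested Gaussian law", {
  spec <- voxel_sim_spec()
  base <- simulate_voxel_series(spec, variance = 0, seed = 17)
  resid <- replicate(950, {
    s <- simulate_voxel_series(spec, variance = 9, truth = base$truth)
    s$series$magnitude - base$noiseless
  })
  # ~1e5 pooled draws: the sample variance matches within 2%
  expect_equal(var(as.vector(resid)), 9, tolerance = 0.02)
  expect_equal(mean(as.vector(resid)), 0, tolerance = 0.05)
})

test_that("SNR in dB follows the power ratio and the calibrated mapping", {
  expect_equal(compute_snr_db(rep(10, 4), 1), 20)
  expect_equal(compute_snr_db(sqrt(10), 10), 0)
  expect_identical(compute_snr_db(rep(10, 4), 0), Inf)
  expect_error(compute_snr_db(rep(10, 4), -1), "variance")
  sim <- simulate_voxel_series(voxel_sim_spec(), variance = 0.1, seed = 3)
  expect_equal(sim$snr_db, 61, tolerance = 0.05)
  # 10 dB per decade of variance at fixed signal
  s <- compute_snr_db(sim$noiseless, 0.1) - compute_snr_db(sim$noiseless, 1)
  expect_equal(s, 10, tolerance = 1e-9)
})

test_that("voxel dataset round-trips through CSV", {
  sim <- simulate_voxel_series(voxel_sim_spec(), variance = 1, seed = 21)
  dir <- withr::local_tempdir()
  write_voxel_dataset(sim, dir)
  back <- read_voxel_series(file.path(dir, "series.csv"))
  expect_equal(back$ti_ms, sim$series$ti_ms)
  expect_equal(back$magnitude, sim$series$magnitude, tolerance = 1e-12)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$truth$t1_ms, sim$truth$t1_ms)
})

test_that("phantom voxels follow the closed-form two-pool signal", {
  spec <- phantom_spec(matrix_size = 16, object_radius = 6)
  ph <- simulate_phantom(spec, seed = 1)
  expect_equal(dim(ph$data), c(16, 16, 1, 70))
  # per-pool oracle at the 700 ms null point: only the 800 ms pool remains
  ti0 <- 700 * log(2)
  oracle <- spec$amplitude * 0.6 * exp(-30 / 90) * abs(1 - 2 * exp(-ti0 / 800))
  direct <- spec$amplitude *
    sum(spec$pools$density * exp(-30 / spec$pools$t2_ms) *
          abs(1 - 2 * exp(-ti0 / spec$pools$t1_ms)))
  expect_equal(direct, oracle, tolerance = 1e-12)
  # on-grid voxel values equal the same closed form at each grid TI
  k <- 30
  expected_k <- spec$amplitude *
    sum(spec$pools$density * exp(-30 / spec$pools$t2_ms) *
          abs(1 - 2 * exp(-ph$ti_ms[k] / spec$pools$t1_ms)))
  expect_equal(ph$data[8, 8, 1, k], expected_k, tolerance = 1e-12)
  # identical composition gives identical time courses without noise
  expect_equal(ph$data[8, 8, 1, ], ph$data[7, 9, 1, ])
  # ground-truth densities sum to one in every fully covered voxel
  sums <- ph$truth |>
    dplyr::filter(.data$coverage >= 1 - 1e-9) |>
    dplyr::summarise(s = sum(.data$density), .by = c("x", "y", "z"))
  expect_true(all(abs(sums$s - 1) < 1e-9))
})

test_that("phantom noise modes are reproducible and Rician-positive", {
  spec <- phantom_spec(matrix_size = 8, object_radius = 3,
                       noise_mode = "rician", noise_sd = 1)
  a <- simulate_phantom(spec, seed = 11)
  b <- simulate_phantom(spec, seed = 11)
  expect_identical(a$data, b$data)
  expect_true(all(a$data >= 0))
  c <- simulate_phantom(spec, seed = 12)
  expect_false(identical(a$data, c$data))
})

test_that("resampled object rendering creates partial-volume edges", {
  spec <- phantom_spec(matrix_size = 16, object_radius = 6,
                       object_grid_size = 100)
  cov <- irlayers:::phantom_coverage(spec)
  expect_true(any(cov > 0 & cov < 1))   # fractional edge voxels
  expect_true(any(cov == 1))            # full interior
  expect_true(all(cov >= 0 & cov <= 1))
})

test_that("phantom specification is validated", {
  expect_error(phantom_spec(pools = tibble::tibble(
    t1_ms = c(700, 800), t2_ms = c(80, 90), density = c(0.5, 0.6))),
    "sum to 1")
  expect_error(phantom_spec(n_ti = 1), "n_ti")
  expect_error(phantom_spec(object_radius = 100), "geometry")
})
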