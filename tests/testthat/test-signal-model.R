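test_that("component kernel hits its null point, origin value and bounds", {
  # null point at TI = T1 * log(2)
  expect_equal(ir_component_signal(1, 700, 700 * log(2)), 0, tolerance = 1e-12)
  # at TI = 0 the kernel magnitude is |1 - 2| = 1
  expect_equal(ir_component_signal(5, 700, 0), 5)
  # frozen high-precision value: 2 * |1 - 2 exp(-3)|
  expect_equal(ir_component_signal(2, 1000, 3000), 1.8008517265285442,
               tolerance = 1e-12)
  # kernel bounded by m0 on a broad grid
  ti <- seq(0, 20000, length.out = 400)
  s <- ir_component_signal(3.5, 1234, ti)
  expect_true(all(s >= 0 & s <= 3.5))
})

test_that("component kernel rejects invalid domains", {
  expect_error(ir_component_signal(1, 0, 100), "t1_ms")
  expect_error(ir_component_signal(1, -5, 100), "t1_ms")
  expect_error(ir_component_signal(-1, 700, 100), "m0")
  expect_error(ir_component_signal(1, 700, -1), "ti_ms")
})

test_that("forward signal sums component kernels and vectorizes", {
  params <- tibble::tibble(m0 = c(1, 1), t1_ms = c(700, 1400))
  # at the 700 ms null point only the 1400 ms term remains: |1 - sqrt(2)|
  expect_equal(ir_signal(params, 700 * log(2)), sqrt(2) - 1, tolerance = 1e-9)
  # at very long TI the exponential vanishes and the signal approaches sum(m0)
  p7 <- tibble::tibble(m0 = 1:7, t1_ms = c(700, 800, 1100, 1200, 1500, 1700, 2000))
  expect_equal(ir_signal(p7, 1e6), sum(p7$m0), tolerance = 1e-6)
  # vectorization agrees with per-point evaluation
  ti <- c(50, 485.2, 1500, 3000)
  expect_equal(ir_signal(params, ti),
               vapply(ti, function(t) ir_signal(params, t), 0))
})

test_that("forward signal validates parameters", {
  expect_error(ir_signal(tibble::tibble(m0 = numeric(), t1_ms = numeric()), 100),
               "at least one component")
  p8 <- tibble::tibble(m0 = rep(1, 8), t1_ms = seq(500, 2500, length.out = 8))
  expect_error(ir_signal(p8, 100), "at most 7")
  expect_error(ir_signal(tibble::tibble(m0 = 1, t1_ms = -1), 100), "t1_ms")
})

test_that("objective is permutation invariant and zero only at a perfect fit", {
  set.seed(11)
  truth <- tibble::tibble(m0 = runif(4, 10, 100),
                          t1_ms = c(700, 1100, 1500, 2000))
  ti <- ti_grid(40, 50, 3000)
  series <- make_series(truth, ti)
  expect_equal(ir_objective(series, truth), 0)
  for (i in 1:5) {
    perm <- sample(4)
    expect_equal(ir_objective(series, truth[perm, ]), 0)
  }
  # residuals with all-zero m0 return the data; perturbations leave a mark
  zero <- tibble::tibble(m0 = rep(0, 4), t1_ms = truth$t1_ms)
  expect_equal(ir_residuals(series, zero), series$magnitude)
  pert <- truth
  pert$t1_ms[2] <- pert$t1_ms[2] * 1.05
  expect_gt(sqrt(sum(ir_residuals(series, pert)^2)), 0)
})

test_that("objective handles degenerate series and mismatched inputs", {
  truth <- tibble::tibble(m0 = 2, t1_ms = 900)
  one <- tibble::tibble(ti_ms = 100, magnitude = 5)
  r1 <- 5 - ir_signal(truth, 100)
  expect_equal(ir_objective(one, truth), r1^2)
  bad <- tibble::tibble(ti_ms = c(100, 50), magnitude = c(1, 2))
  expect_error(ir_residuals(bad, truth), "strictly increasing")
  expect_error(ir_residuals(tibble::tibble(ti_ms = 1, mag = 2), truth),
               "magnitude")
})

test_that("analytic Jacobian matches its closed-form corners", {
  params <- tibble::tibble(m0 = c(2, 3), t1_ms = c(700, 1500))
  J0 <- ir_jacobian(params, 0)
  expect_equal(unname(J0[1, 1:2]), c(1, 1))   # d/dM0 at TI = 0 is |1-2| = 1
  # T1 derivative vanishes at the component's null point (sign(0) = 0)
  Jn <- ir_jacobian(params, 700 * log(2))
  expect_equal(unname(Jn[1, 3]), 0)
  expect_equal(dim(ir_jacobian(params, ti_grid(10, 50, 3000))), c(10L, 4L))
})

test_that("Jacobian agrees with central finite differences away from kinks", {
  set.seed(42)
  ti <- ti_grid(60, 50, 3000)
  for (rep_i in 1:20) {
    n <- sample(1:4, 1)
    params <- random_params_off_kink(ti, n)
    J <- ir_jacobian(params, ti)
    Jfd <- fd_jacobian(params, ti)
    scale <- max(abs(Jfd), 1)
    expect_lt(max(abs(J - Jfd)) / scale, 1e-5)
  }
})

test_that("gradient and Gauss-Newton Hessian follow from the Jacobian", {
  set.seed(3)
  truth <- tibble::tibble(m0 = c(50, 80), t1_ms = c(800, 1600))
  ti <- ti_grid(30, 50, 3000)
  series <- make_series(truth, ti)
  probe <- tibble::tibble(m0 = c(60, 70), t1_ms = c(900, 1500))
  r <- ir_residuals(series, probe)
  J <- ir_jacobian(probe, ti)
  expect_equal(ir_gradient(series, probe), as.vector(-2 * crossprod(J, r)))
  expect_equal(ir_gn_hessian(probe, ti), 2 * crossprod(J))
  # gradient is zero at the (noiseless) truth
  expect_equal(ir_gradient(series, truth), rep(0, 4), tolerance = 1e-10)
})
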