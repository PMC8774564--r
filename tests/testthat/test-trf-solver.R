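test_that("quadratic model reproduces the objective at zero step and is Taylor-exact", {
  set.seed(7)
  g <- rnorm(4)
  A <- matrix(rnorm(16), 4)
  H <- crossprod(A) + diag(4)
  f0 <- 3.25
  m <- tr_quadratic_model(f0, g, H)
  expect_equal(m(rep(0, 4)), f0)
  # for a quadratic objective with its exact Hessian the model is exact
  fq <- function(x) f0 + sum(g * x) + 0.5 * sum(x * (H %*% x))
  for (i in 1:5) {
    s <- rnorm(4)
    expect_equal(m(s), fq(s), tolerance = 1e-12)
  }
  # linear objective: H = 0
  ml <- tr_quadratic_model(f0, g, matrix(0, 4, 4))
  s <- rnorm(4)
  expect_equal(ml(s), f0 + sum(g * s))
  expect_error(tr_quadratic_model(f0, c(1, NaN), diag(2)), "non-finite")
})

test_that("2D-subspace step solves the identity-Hessian cases exactly", {
  # Newton step is (-1, 0); radius 0.5 truncates it along -g
  expect_equal(tr_subproblem_2d(c(1, 0), diag(2), 0.5), c(-0.5, 0))
  # radius 2 admits the interior Newton step
  expect_equal(tr_subproblem_2d(c(1, 0), diag(2), 2), c(-1, 0))
  # zero gradient: zero step (first-order stationary)
  expect_equal(tr_subproblem_2d(c(0, 0), diag(2), 1), c(0, 0))
})

test_that("2D-subspace step is within the region and never worse than Cauchy", {
  set.seed(21)
  for (i in 1:40) {
    p <- sample(c(2, 4, 6), 1)
    g <- rnorm(p)
    A <- matrix(rnorm(p * p), p)
    B <- if (i %% 3 == 0) crossprod(A) else (A + t(A)) / 2  # PSD or indefinite
    radius <- runif(1, 0.05, 2)
    s <- tr_subproblem_2d(g, B, radius)
    expect_lte(sqrt(sum(s^2)), radius * (1 + 1e-9))
    sc <- cauchy_step(g, B, radius)
    expect_lte(quad_value(g, B, s), quad_value(g, B, sc) + 1e-10)
  }
})

test_that("for p = 2 the subspace step attains the exact subproblem optimum", {
  set.seed(5)
  for (i in 1:25) {
    g <- rnorm(2)
    A <- matrix(rnorm(4), 2)
    B <- (A + t(A)) / 2
    radius <- runif(1, 0.1, 1.5)
    s <- tr_subproblem_2d(g, B, radius)
    oracle <- trs_oracle_2d(g, B, radius)
    expect_lte(quad_value(g, B, s), oracle + 1e-6 * max(1, abs(oracle)))
  }
})

test_that("step quality ratio and radius policy behave as specified", {
  ctrl <- trf_control()
  # exact quadratic prediction gives rho = 1
  expect_equal(tr_step_quality(10, 6, 4), 1)
  # objective increase gives a negative ratio
  expect_lt(tr_step_quality(10, 12, 4), 0)
  # non-positive predicted reduction rejects outright
  expect_identical(tr_step_quality(10, 9, 0), -Inf)
  # bookkeeping identity
  expect_equal(tr_step_quality(7, 5.5, 3), (7 - 5.5) / 3)

  # very good model agreement on a boundary step doubles the radius
  up <- tr_update_radius(ctrl, rho = 0.9, step_norm = 1, radius = 1)
  expect_true(up$accepted)
  expect_equal(up$radius, 2)
  # poor agreement shrinks towards the attempted step but keeps the gain
  up <- tr_update_radius(ctrl, rho = 0.05, step_norm = 0.5, radius = 1)
  expect_true(up$accepted)
  expect_equal(up$radius, 0.25 * 0.5)
  # an objective increase is rejected and the radius shrinks
  up <- tr_update_radius(ctrl, rho = -0.3, step_norm = 1, radius = 1)
  expect_false(up$accepted)
  expect_equal(up$radius, 0.25)
  # moderate agreement on an interior step leaves the radius unchanged
  up <- tr_update_radius(ctrl, rho = 0.5, step_norm = 0.2, radius = 1)
  expect_true(up$accepted)
  expect_equal(up$radius, 1)
})

test_that("single-start solve recovers a 1-component truth and beats a dense grid", {
  truth <- tibble::tibble(m0 = 100, t1_ms = 1000)
  ti <- ti_grid(105, 50, 3000)
  series <- make_series(truth, ti)
  bounds <- ir_bounds(series, 1, m0_lower = 0, m0_upper = 200)
  fit <- ir_fit(series, 1, bounds = bounds, starts = matrix(c(80, 800), 1))
  expect_equal(fit$params$m0, 100, tolerance = 1e-6)
  expect_equal(fit$params$t1_ms, 1000, tolerance = 1e-6)
  # the dense 2000 x 2000 grid oracle confirms this is the global optimum
  oracle <- grid_oracle_1c(series,
                           m0_grid = seq(0.1, 200, length.out = 2000),
                           t1_grid = seq(250, 4000, length.out = 2000))
  expect_lte(fit$objective, oracle$objective + 1e-9)
  expect_equal(oracle$m0, 100, tolerance = 0.11)
  expect_equal(oracle$t1_ms, 1000, tolerance = 2)
})

test_that("starting at the optimum terminates immediately with a zero step", {
  truth <- tibble::tibble(m0 = c(60, 40), t1_ms = c(700, 1400))
  ti <- ti_grid(40, 50, 3000)
  series <- make_series(truth, ti)
  bounds <- ir_bounds(series, 2)
  res <- irlayers:::ir_solve_one(series, 2, c(60, 40, 700, 1400), bounds)
  expect_true(res$converged)
  expect_lte(res$iterations, 2)
  expect_equal(res$x, c(60, 40, 700, 1400), tolerance = 1e-8)
})

test_that("generic interface minimizes a bounded Rosenbrock problem", {
  rosen_r <- function(x) c(10 * (x[2] - x[1]^2), 1 - x[1])
  rosen_j <- function(x) matrix(c(-20 * x[1], -1, 10, 0), 2, 2)
  res <- trf_minimize(rosen_r, rosen_j, c(-1.2, 1), c(-2, -2), c(2, 2))
  expect_true(res$converged)
  expect_equal(res$x, c(1, 1), tolerance = 1e-6)
  # accepted objective values never increase
  expect_true(all(diff(res$trace) <= 0))
})

test_that("start sampling respects bounds, the seed, and the prefix property", {
  bounds <- ir_bounds(n_components = 3, m0_upper = 50)
  s1 <- with(list(), { set.seed(123); sample_starts(bounds, 10) })
  s2 <- with(list(), { set.seed(123); sample_starts(bounds, 10) })
  expect_identical(s1, s2)
  s20 <- with(list(), { set.seed(123); sample_starts(bounds, 20) })
  expect_identical(s20[1:10, ], s1)  # nested prefix under the same seed
  bv <- irlayers:::bounds_vectors(bounds)
  expect_true(all(sweep(s20, 2, bv$lower, ">=") & sweep(s20, 2, bv$upper, "<=")))
})

test_that("multistart reduces to the single solve and improves monotonically", {
  truth <- tibble::tibble(m0 = c(60, 40), t1_ms = c(700, 1400))
  ti <- ti_grid(50, 50, 3000)
  series <- make_series(truth, ti)
  bounds <- ir_bounds(series, 2)
  start1 <- with(list(), { set.seed(77); sample_starts(bounds, 1) })
  f_multi <- ir_fit(series, 2, bounds = bounds, n_starts = 1, seed = 77)
  f_single <- ir_fit(series, 2, bounds = bounds, starts = start1)
  expect_equal(f_multi$objective, f_single$objective)
  expect_equal(f_multi$params, f_single$params)
  # nested start sets: the best objective is non-increasing in n_starts
  objs <- vapply(c(1, 5, 15, 40),
                 function(k) ir_fit(series, 2, bounds = bounds,
                                    n_starts = k, seed = 42)$objective, 0)
  expect_true(all(diff(objs) <= 1e-12))
  # same seed reproduces the fit exactly
  f_a <- ir_fit(series, 2, bounds = bounds, n_starts = 10, seed = 9)
  f_b <- ir_fit(series, 2, bounds = bounds, n_starts = 10, seed = 9)
  expect_identical(f_a$params, f_b$params)
})

test_that("fitted parameters always satisfy the bounds", {
  set.seed(31)
  spec <- voxel_sim_spec()
  sim <- simulate_voxel_series(spec, variance = 100, seed = 8)
  bounds <- ir_bounds(sim$series, 7)
  fit <- ir_fit(sim$series, 7, bounds = bounds, n_starts = 10, seed = 4)
  bv <- irlayers:::bounds_vectors(bounds)
  x <- c(fit$params$m0, fit$params$t1_ms)
  # components are reported sorted by T1; bounds are uniform per family
  expect_true(all(x >= bv$lower - 1e-12 * abs(bv$lower)))
  expect_true(all(x <= bv$upper + 1e-12 * abs(bv$upper)))
})

test_that("noiseless 1-3 component fits with 100 starts recover all coefficients", {
  set.seed(2026)
  ti <- ti_grid(60, 50, 3000)
  t1_sets <- list(1300, c(700, 1600), c(700, 1200, 2000))
  for (n in 1:3) {
    truth <- tibble::tibble(m0 = runif(n, 30, 120), t1_ms = t1_sets[[n]])
    series <- make_series(truth, ti)
    # the magnitude maximum can sit below an individual M0 for few
    # components, so give the box explicit headroom above the truth
    bounds <- ir_bounds(series, n, m0_lower = 1, m0_upper = 150)
    fit <- ir_fit(series, n, bounds = bounds, n_starts = 100, seed = 100 + n)
    err <- component_errors(fit, truth)
    expect_lt(max(err$rel_error_pct), 0.1)
  }
})

test_that("2-component multistart attains the grid-search oracle optimum", {
  truth <- tibble::tibble(m0 = c(70, 30), t1_ms = c(800, 1800))
  ti <- ti_grid(50, 50, 3000)
  series <- make_series(truth, ti)
  fit <- ir_fit(series, 2, n_starts = 15, seed = 12)
  oracle_best <- grid_oracle_2c(series,
                                m0_grid = seq(1, 110, length.out = 40),
                                t1_grid = seq(250, 4000, length.out = 40))
  expect_lte(fit$objective, oracle_best + 1e-9)
})

test_that("the identifiability floor rejects short series", {
  truth <- tibble::tibble(m0 = c(60, 40), t1_ms = c(700, 1400))
  short <- make_series(truth, ti_grid(3, 50, 3000))
  expect_error(ir_fit(short, 2, bounds = ir_bounds(short, 2)),
               "requires at least 4")
})

test_that("solver diagnostics record per-start outcomes", {
  truth <- tibble::tibble(m0 = c(60, 40), t1_ms = c(700, 1400))
  series <- make_series(truth, ti_grid(30, 50, 3000))
  fit <- ir_fit(series, 2, n_starts = 8, seed = 5)
  expect_equal(nrow(fit$starts), 8)
  expect_equal(fit$objective, min(fit$starts$objective))
  expect_true(all(fit$starts$iterations >= 0))
  g <- glance(fit)
  expect_equal(g$n_starts, 8L)
  expect_equal(g$objective, fit$objective)
  expect_equal(tidy(fit), fit$params)
})
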