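# Independent oracles used to cross-check the solver and model code.

# Noiseless series from a ground truth on a TI grid.
make_series <- function(truth, ti) {
  tibble::tibble(ti_ms = ti, magnitude = ir_signal(truth, ti))
}

# Dense grid-search oracle for the 1-component fit. Uses the closed form
# f(a, b) = sum(y^2) - 2 a c1(b) + a^2 c2(b) with the kernel column sums
# precomputed, so a 2000 x 2000 grid is cheap.
grid_oracle_1c <- function(series, m0_grid, t1_grid) {
  y <- series$magnitude
  K <- abs(1 - 2 * exp(-outer(series$ti_ms, t1_grid, "/")))
  c1 <- as.vector(crossprod(y, K))
  c2 <- colSums(K^2)
  f <- sum(y^2) - 2 * outer(m0_grid, c1) + outer(m0_grid^2, c2)
  best <- arrayInd(which.min(f), dim(f))
  list(objective = f[best],
       m0 = m0_grid[best[1]], t1_ms = t1_grid[best[2]])
}

# Grid-search oracle for the 2-component fit (same closed form extended
# with the kernel cross term).
grid_oracle_2c <- function(series, m0_grid, t1_grid) {
  y <- series$magnitude
  K <- abs(1 - 2 * exp(-outer(series$ti_ms, t1_grid, "/")))
  c1 <- as.vector(crossprod(y, K))
  c2 <- colSums(K^2)
  C12 <- crossprod(K)
  y2 <- sum(y^2)
  nt <- length(t1_grid)
  ones <- rep(1, length(m0_grid))
  A <- outer(m0_grid, ones)      # first-component m0 along rows
  Bm <- t(A)                     # second-component m0 along columns
  best <- Inf
  for (i in seq_len(nt)) for (j in i:nt) {
    f <- y2 - 2 * (A * c1[i] + Bm * c1[j]) +
      A^2 * c2[i] + Bm^2 * c2[j] + 2 * A * Bm * C12[i, j]
    m <- min(f)
    if (m < best) best <- m
  }
  best
}

# Optimal step along the negative gradient within the trust region
# (closed-form Cauchy point).
cauchy_step <- function(g, B, radius) {
  gn2 <- sum(g^2)
  if (gn2 == 0) return(rep(0, length(g)))
  gBg <- sum(g * (B %*% g))
  t_tr <- radius / sqrt(gn2)
  t <- if (gBg > 0) min(gn2 / gBg, t_tr) else t_tr
  -t * g
}

quad_value <- function(g, B, s) sum(g * s) + 0.5 * sum(s * (B %*% s))

# Brute-force oracle for the p = 2 trust-region subproblem: interior
# Newton point (when admissible) and a fine sweep of the boundary circle.
trs_oracle_2d <- function(g, B, radius, n_angles = 36000) {
  th <- seq(0, 2 * pi, length.out = n_angles)
  pts <- radius * rbind(cos(th), sin(th))
  vals <- as.vector(t(pts) %*% g) + 0.5 * colSums(pts * (B %*% pts))
  best <- min(vals)
  ev <- eigen(B, symmetric = TRUE)$values
  if (min(ev) > 0) {
    s <- -solve(B, g)
    if (sqrt(sum(s^2)) <= radius) best <- min(best, quad_value(g, B, s))
  }
  best
}

# Central finite-difference Jacobian of the forward model.
fd_jacobian <- function(params, ti, h_rel = 1e-4) {
  n <- nrow(params)
  x <- c(params$m0, params$t1_ms)
  J <- matrix(0, length(ti), 2 * n)
  for (k in seq_along(x)) {
    h <- h_rel * max(abs(x[k]), 1)
    xp <- x; xm <- x
    xp[k] <- x[k] + h; xm[k] <- x[k] - h
    pp <- tibble::tibble(m0 = xp[1:n], t1_ms = xp[n + 1:n])
    pm <- tibble::tibble(m0 = xm[1:n], t1_ms = xm[n + 1:n])
    J[, k] <- (ir_signal(pp, ti) - ir_signal(pm, ti)) / (2 * h)
  }
  J
}

# Random bounded parameter point whose kernels stay away from the
# absolute-value kink on the given grid.
random_params_off_kink <- function(ti, n, min_kernel = 5e-3) {
  repeat {
    t1 <- runif(n, 300, 3800)
    k <- 1 - 2 * exp(-outer(ti, t1, "/"))
    if (min(abs(k)) > min_kernel) break
  }
  tibble::tibble(m0 = runif(n, 10, 200), t1_ms = t1)
}
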