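test_that("regularized delta is a compactly supported partition of unity", {
  expect_identical(delta_weight(2.5), 0)
  expect_identical(delta_weight(-2), 0)
  expect_equal(delta_weight(0), 0.5)
  expect_equal(delta_weight(0)^2, 0.25)  # 2D weight at a coincident node
  set.seed(7)
  for (a in runif(8)) {
    w <- delta_weight((-2:2) - a)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    # even and odd translates each sum to 1/2 (kills the checkerboard mode)
    expect_equal(sum(w[c(1, 3, 5)]), 0.5, tolerance = 1e-12)
    expect_equal(sum(w[c(2, 4)]), 0.5, tolerance = 1e-12)
  }
})

test_that("spreading conserves totals and matches the direct-summation oracle", {
  g <- fluid_grid(32, 20)
  # one point exactly on a node, unit value
  g1 <- spread(g, matrix(c(5, 5), 1), 1, target = "source")
  expect_equal(sum(g1$s) * g1$h^2, 1, tolerance = 1e-13)
  # antisymmetric forces cancel
  pos <- matrix(c(7.3, 8.1, 7.3, 8.1), 2, 2, byrow = TRUE)
  g2 <- spread(g, pos, rbind(c(2, -1), c(-2, 1)), target = "force")
  expect_equal(max(abs(g2$fx)), 0)
  expect_equal(max(abs(g2$fy)), 0)
  # off-node points against the naive O(N * grid) oracle
  set.seed(11)
  pts <- matrix(runif(10, 2, 18), 5, 2)
  val <- rnorm(5)
  g3 <- spread(g, pts, val, target = "source")
  expect_equal(g3$s, spread_oracle(pts, val, 32, g$h), tolerance = 1e-12)
  expect_equal(sum(g3$s) * g3$h^2, sum(val), tolerance = 1e-12)
  # non-finite positions are a defect
  expect_error(spread(g, matrix(c(NA, 1), 1), 1, "source"), "non-finite")
})

test_that("fluid solve satisfies the mass balance div u = s at every node", {
  g <- fluid_grid(64, 40)
  # nothing in, nothing out
  g0 <- solve_fluid_step(g)
  expect_equal(max(abs(g0$u)), 0)
  expect_equal(max(abs(g0$v)), 0)
  # balanced source/sink pair
  g1 <- spread(g, rbind(c(17, 20), c(23, 20)), c(2, -2), target = "source")
  g1 <- solve_fluid_step(g1)
  dv <- grid_divergence(g1)
  expect_lt(max(abs(dv - g1$s)) / max(abs(g1$s)), 1e-10)
  expect_lt(abs(sum(dv)), 1e-10)
  # discrete divergence theorem: net flux out of a box containing only the
  # source equals its strength (block sum computed with an independent
  # finite-difference divergence)
  ind_div <- function(u, v, h) {
    n <- nrow(u); ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
    (u[ip, ] - u[im, ]) / (2 * h) + (v[, ip] - v[, im]) / (2 * h)
  }
  dv2 <- ind_div(g1$u, g1$v, g1$h)
  blk <- which(abs(seq(0, by = g1$h, length.out = 64) - 17) < 2.6)
  flux <- sum(dv2[blk, which(abs(seq(0, by = g1$h, length.out = 64) - 20) < 2.6)]) * g1$h^2
  expect_equal(flux, 2, tolerance = 1e-8)
})

test_that("spread and interpolation are discrete adjoints", {
  g <- fluid_grid(32, 20)
  set.seed(3)
  U <- matrix(rnorm(32^2), 32); V <- matrix(rnorm(32^2), 32)
  pts <- matrix(runif(16, 1, 19), 8, 2)
  F <- matrix(rnorm(16), 8, 2)
  gf <- spread(g, pts, F, target = "force")
  gv <- g; gv$u <- U; gv$v <- V
  lhs <- sum(gf$fx * U + gf$fy * V) * g$h^2
  rhs <- sum(F * interpolate_velocity(gv, pts))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("velocity interpolation is exact on uniform fields and matches the oracle", {
  g <- fluid_grid(32, 20)
  g$u <- matrix(3.5, 32, 32); g$v <- matrix(0, 32, 32)
  pts <- rbind(c(5, 5), c(7.123, 9.771), c(0.6, 19.2))
  vel <- interpolate_velocity(g, pts)
  expect_equal(vel[, 1], rep(3.5, 3), tolerance = 1e-12)
  expect_equal(vel[, 2], rep(0, 3))
  # generic points against a direct-summation oracle over all nodes
  set.seed(5)
  g$u <- matrix(rnorm(32^2), 32); g$v <- matrix(rnorm(32^2), 32)
  oracle <- function(field, p) {
    tot <- 0
    for (i in 1:32) for (j in 1:32) {
      wx <- delta_weight(((i - 1) * g$h - p[1]) / g$h)
      wy <- delta_weight(((j - 1) * g$h - p[2]) / g$h)
      tot <- tot + field[i, j] * wx * wy
    }
    tot
  }
  vel2 <- interpolate_velocity(g, pts)
  for (r in 1:2) {
    expect_equal(vel2[r, 1], oracle(g$u, pts[r, ]), tolerance = 1e-12)
    expect_equal(vel2[r, 2], oracle(g$v, pts[r, ]), tolerance = 1e-12)
  }
})

test_that("advection is forward Euler with periodic wrap and O(dt) accuracy", {
  g <- fluid_grid(32, 20)
  pts <- rbind(c(1, 1), c(19.5, 10))
  expect_equal(advect(pts, matrix(0, 2, 2), 0.1, g), pts)
  # constant velocity accumulates c * T over many steps (with wrap)
  p <- matrix(c(5, 5), 1)
  for (k in 1:100) p <- advect(p, matrix(c(0.3, 0), 1), 0.1, g)
  expect_equal(p[1, 1], (5 + 0.3 * 10) %% 20, tolerance = 1e-10)
  # rigid rotation: radius drift shrinks linearly with dt
  drift <- function(dt) {
    ctr <- c(10, 10); p <- matrix(c(14, 10), 1)
    for (k in seq_len(round(2 / dt))) {
      v <- cbind(-(p[1, 2] - ctr[2]), p[1, 1] - ctr[1])
      p <- advect(p, v, dt, g, warn = FALSE)
    }
    abs(sqrt(sum((p[1, ] - ctr)^2)) - 4)
  }
  d1 <- drift(0.02); d2 <- drift(0.01)
  expect_lt(d2, d1)
  expect_equal(d1 / d2, 2, tolerance = 0.25)
})

test_that("a quiescent membrane at rest length induces no flow", {
  cfg <- sim_config(grid_n = 64, domain_um = 40, cell_diameter_um = 10,
                    E = 0, t_end_days = 1)   # E = 0: instant ECM arrest
  st <- init_state(cfg)
  for (k in 1:20) st <- sim_step(st)
  expect_lt(max(abs(st$grid$u), abs(st$grid$v)), 1e-4)
})
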