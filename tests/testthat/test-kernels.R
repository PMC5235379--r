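test_that("step_params derives the CFL number", {
  p <- step_params(h = 1 / 12, dx = 1 / 5)
  expect_equal(p$k, (1 / 12) / (2 * (1 / 5)^2))  # k = h / (2 dx^2), scaled units
  p2 <- step_params(h = 25, dx = 56, c = 95, lam = 2.04e-3)
  expect_equal(p2$k, 95 * 25 / 56^2)
  expect_error(step_params(h = 0, dx = 1), "positive")
})

test_that("diffusion_operator applies the raw (1,-2,1) stencil", {
  expect_equal(diffusion_operator(c(1, 1, 1)), c(-1, 0, -1))
  expect_equal(diffusion_operator(c(0, 1, 0)), c(1, -2, 1))
  expect_equal(diffusion_operator(c(1, 2, 3)), c(0, 0, -4))
  expect_equal(diffusion_operator(2), -4)
})

test_that("solve_tridiagonal matches a dense solve and survives weak pivots", {
  expect_equal(solve_tridiagonal(numeric(0), 1, numeric(0), 3), 3)
  expect_equal(solve_tridiagonal(1, c(2, 2), 1, c(3, 3)), c(1, 1))
  set.seed(3)
  for (trial in 1:5) {
    n <- 6
    sub <- runif(n - 1, -1, 1)
    super <- runif(n - 1, -1, 1)
    dg <- 3 + runif(n)
    rhs <- rnorm(n)
    M <- diag(dg)
    M[cbind(2:n, 1:(n - 1))] <- sub
    M[cbind(1:(n - 1), 2:n)] <- super
    expect_lt(max(abs(solve_tridiagonal(sub, dg, super, rhs) -
                        solve(M, rhs))), 1e-12)
  }
  # first pivot ~0 triggers the dense fallback; system is still solvable
  x <- solve_tridiagonal(c(1, 1), c(0, 2, 2), c(1, 1), c(1, 2, 3))
  M <- rbind(c(0, 1, 0), c(1, 2, 1), c(0, 1, 2))
  expect_equal(x, as.numeric(solve(M, c(1, 2, 3))))
  expect_error(solve_tridiagonal(numeric(0), 0, numeric(0), 1), "singular")
})

test_that("euler_predictor honors fixed points, the hand example and clamps", {
  p <- step_params(h = 0.1, dx = 1, c = 0.5, lam = 1)
  expect_equal(euler_predictor(rep(0, 5), rep(1, 5), p, "neumann"), rep(0, 5))
  # constant at capacity is untouched under zero-flux ghosts
  expect_equal(euler_predictor(rep(0.8, 5), rep(0.8, 5), p, "neumann"),
               rep(0.8, 5))
  # single cell, no diffusion: uE = u + h (1 - u) u
  p0 <- step_params(h = 0.1, dx = 1, c = 0, lam = 1)
  expect_equal(euler_predictor(0.5, 1, p0, "neumann"), 0.525)
  # clamped to K_th
  expect_lte(max(euler_predictor(c(0.1, 0.9, 0.1), rep(1, 3), p, "neumann",
                                 K_th = rep(0.5, 3))), 0.5)
  expect_error(euler_predictor(0.5, 0, p, "neumann"), "positive")
})

test_that("Dirichlet trapezoid preserves zero and pulls the ends below K", {
  p <- step_params(h = 1 / 12, dx = 1 / 5)
  n <- 30
  z <- rep(0, n)
  expect_equal(trapezoid_step_dirichlet(z, z, rep(1, n), rep(1, n), p), z)
  u <- rep(1, n)
  uE <- euler_predictor(u, rep(1, n), p, "dirichlet")
  out <- trapezoid_step_dirichlet(u, uE, rep(1, n), rep(1, n), p)
  # interior barely moves, padded-zero ends drag coastal cells down
  expect_gt(min(out[10:20]), 1 - 1e-4)
  expect_lt(out[1], 0.95)
  expect_lt(out[n], 0.95)
})

test_that("Neumann assembly matches the dense bandwidth-5 solve to O(h^2)", {
  p <- step_params(h = 0.05, dx = 0.5)
  n <- 8
  u <- 0.4 + 0.2 * sin(seq(0, pi, length.out = n))
  Kt <- rep(1, n)
  uE <- euler_predictor(u, Kt, p, "neumann")
  x_tri <- assemble_neumann_step(u, uE, Kt, Kt, p)
  x_dense <- dense_neumann_solve(u, uE, Kt, Kt, p)
  expect_lt(max(abs(x_tri - x_dense)), p$h^2)
  # post-solve end refresh makes no discernible difference
  x_ref <- assemble_neumann_step(u, uE, Kt, Kt, p, refresh_ends = TRUE)
  expect_lt(max(abs(x_tri - x_ref)), 1e-3)
  # fixed points
  expect_equal(assemble_neumann_step(rep(0, n), rep(0, n), Kt, Kt, p),
               rep(0, n))
  expect_equal(assemble_neumann_step(Kt, Kt, Kt, Kt, p), Kt,
               tolerance = 1e-13)
  expect_error(assemble_neumann_step(u[1:3], uE[1:3], Kt[1:3], Kt[1:3], p),
               "short_segment_step")
})

test_that("short Neumann segments follow their special cases", {
  p <- step_params(h = 0.1, dx = 1, c = 0, lam = 1)
  # n = 1: hand evaluation of the semi-implicit logistic update
  uE <- 0.525
  expected <- (1 + 0.05 * (1 - 0.5)) * 0.5 / (1 - 0.05 * (1 - uE))
  expect_equal(short_segment_step(0.5, 1, 1, p), expected)

  # n = 2: outputs are equal and non-negative
  p2 <- step_params(h = 0.05, dx = 0.5)
  out2 <- short_segment_step(c(0.3, 0.7), c(1, 1), c(1, 1), p2)
  expect_equal(out2[1], out2[2])
  expect_gte(min(out2), 0)

  # n = 3: equals the dense bordered solve, all entries equal
  u3 <- c(0.3, 0.5, 0.4)
  K3 <- rep(1, 3)
  out3 <- short_segment_step(u3, K3, K3, p2)
  expect_equal(diff(range(out3)), 0)
  uE3 <- euler_predictor(u3, K3, p2, "neumann")
  k <- p2$k
  lh <- p2$lam * p2$h
  S1 <- -k / 2
  S2 <- 1 + k - (lh / 2) * (1 - uE3[2])
  M <- rbind(c(1, -4 / 3, 1 / 3), c(S1, S2, S1), c(1 / 3, -4 / 3, 1))
  rhs2 <- u3[2] + (k / 2) * (u3[1] - 2 * u3[2] + u3[3]) +
    (lh / 2) * (1 - u3[2]) * u3[2]
  expect_equal(out3, as.numeric(solve(M, c(0, rhs2, 0))), tolerance = 1e-12)

  expect_error(short_segment_step(rep(0.1, 4), rep(1, 4), rep(1, 4), p2),
               "n_seg <= 3")
})

test_that("u = 0 and u = K are fixed points of every Neumann variant (n != 2)", {
  p <- step_params(h = 1 / 12, dx = 1 / 5)
  for (n in c(1L, 3L, 4L, 8L)) {
    K <- rep(0.9, n)
    expect_equal(kpp_step_1d(rep(0, n), p, K_t = K), rep(0, n))
    expect_equal(kpp_step_1d(K, p, K_t = K), K, tolerance = 1e-13)
  }
  # Dirichlet zero is preserved everywhere
  expect_equal(kpp_step_1d(rep(0, 6), p, K_t = 1, bc = "dirichlet"), rep(0, 6))
})
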