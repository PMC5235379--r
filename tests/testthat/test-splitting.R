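test_that("clamp_to_capacity enforces the stage bounds", {
  u <- matrix(c(-0.1, 1.5, 0.3, 0.2), 2, 2)
  K <- matrix(c(1, 1, 1, 0), 2, 2)
  expect_equal(clamp_to_capacity(u, K), matrix(c(0, 1, 0.3, 0), 2, 2))
  expect_error(clamp_to_capacity(u, matrix(1, 3, 3)), "mismatch")
})

test_that("x half-step fixes zero and constants and reduces to 1-D", {
  isl <- rect_island(12, 16, K = 0.7)
  p <- step_params(h = 0.1, dx = 1, c = 0.5, lam = 1)
  z <- matrix(0, 12, 16)
  expect_equal(diffusion_half_step_x(z, isl$K, isl$segs, p, "neumann"), z)
  expect_equal(diffusion_half_step_x(isl$K, isl$K, isl$segs, p, "neumann"),
               isl$K, tolerance = 1e-13)

  # 1-row domain: two consecutive half-steps agree with one fused full step
  # to O(h^2) on smooth data
  n <- 60
  mask <- matrix(TRUE, 1, n)
  segs <- segment_mask(mask)
  Kr <- matrix(1, 1, n)
  u <- matrix(0.5 + 0.3 * sin(seq(0, 2 * pi, length.out = n)), 1, n)
  ph <- step_params(h = 0.05, dx = 0.5)
  two <- diffusion_half_step_x(
    diffusion_half_step_x(u, Kr, segs, ph, "neumann"), Kr, segs, ph, "neumann")
  one <- diffusion_half_step_x(u, Kr, segs, ph, "neumann", fused = TRUE)
  expect_lt(max(abs(two - one)), ph$h^2)
})

test_that("y predictor matches the hand formula on a single column", {
  mask <- matrix(TRUE, 3, 1)
  segs <- segment_mask(mask)
  u <- matrix(c(0.2, 0.5, 0.3), 3, 1)
  Kt <- matrix(c(1, 0.9, 1), 3, 1)
  Kth <- matrix(c(1, 0.95, 1), 3, 1)
  p <- step_params(h = 0.05, dx = 0.5)
  uE <- predictor_y(u, Kt, Kth, segs, p, "neumann")
  k <- p$k
  lh <- p$lam * p$h
  # mirror ghosts: A u = (2u2 - 2u1, u1 - 2u2 + u3, 2u2 - 2u3)
  expected <- c(u[1] + k * (2 * u[2] - 2 * u[1]) + lh * (1 - u[1] / Kt[1]) * u[1],
                u[2] + k * (u[1] - 2 * u[2] + u[3]) + lh * (1 - u[2] / Kt[2]) * u[2],
                u[3] + k * (2 * u[2] - 2 * u[3]) + lh * (1 - u[3] / Kt[3]) * u[3])
  expected <- pmin(pmax(expected, 0), Kth)
  expect_equal(as.numeric(uE), as.numeric(expected))
  expect_equal(predictor_y(u * 0, Kt, Kth, segs, p, "neumann"),
               matrix(0, 3, 1))
})

test_that("implicit y step on a single column equals the 1-D kernel", {
  n <- 7
  mask <- matrix(TRUE, n, 1)
  segs <- segment_mask(mask)
  u <- matrix(0.3 + 0.2 * cos(seq(0, pi, length.out = n)), n, 1)
  Kt <- matrix(seq(0.8, 1.2, length.out = n), n, 1)
  Kth <- Kt * 1.05
  p <- step_params(h = 0.05, dx = 0.5)
  for (bc in c("neumann", "dirichlet")) {
    uE <- predictor_y(u, Kt, Kth, segs, p, bc)
    out <- implicit_y(u, uE, Kt, Kth, segs, p, bc)
    expect_equal(as.numeric(out),
                 kpp_step_1d(as.numeric(u), p, K_t = as.numeric(Kt),
                             K_th = as.numeric(Kth), bc = bc))
  }
})

test_that("godunov_step preserves fixed points and mirror symmetry", {
  isl <- rect_island(15, 15)
  p <- step_params(h = 0.1, dx = 1, c = 0.5, lam = 1)
  z <- matrix(0, 15, 15)
  expect_equal(godunov_step(z, isl$K, isl$K, isl$segs, p, "neumann"), z)
  u <- isl$K
  for (s in 1:20) u <- godunov_step(u, isl$K, isl$K, isl$segs, p, "neumann")
  expect_lt(max(abs(u - isl$K)), 1e-13)

  seed <- gaussian_seed(isl$K, isl$mask, c(8, 8), 2, 0.5)
  u <- seed
  for (s in 1:100) u <- godunov_step(u, isl$K, isl$K, isl$segs, p, "neumann")
  expect_lt(max(abs(u - u[, 15:1])), 1e-12)
  expect_lt(max(abs(u - u[15:1, ])), 1e-12)
  expect_true(all(u >= 0 & u <= max(isl$K)))
  expect_error(godunov_step(z, isl$K, matrix(1, 2, 2), isl$segs, p), "mismatch")
})

test_that("fused half-steps agree with plain stepping over a trajectory", {
  w <- synthetic_world("corridor", nrows = 1, ncols = 100, K = 1,
                       frame_times = c(0, 5))
  u0 <- matrix(ifelse(seq_len(100) <= 10, 1, 0), 1, 100)
  cfgA <- kpp_config(w$series, r = 1, D = 1, dx = 0.2, h = 1 / 12, t_end = 5,
                     u0 = u0)
  cfgB <- kpp_config(w$series, r = 1, D = 1, dx = 0.2, h = 1 / 12, t_end = 5,
                     u0 = u0, combine_half_steps = TRUE)
  expect_lt(max(abs(run_simulation(cfgA)$u - run_simulation(cfgB)$u)), 1e-3)
})

test_that("split semi-implicit amplification stays below 1 even at k = 1", {
  for (k in c(0.25, 0.5, 1, 2)) {
    expect_lte(split_step_gain(k), 1 + 1e-12)
  }
})

test_that("2-D solution matches the radial method-of-lines reference", {
  n <- 81
  dx <- 0.2
  K <- matrix(1, n, n)
  segs <- segment_mask(K > 0)
  ctr <- (n + 1) / 2
  xs <- ((1:n) - ctr) * dx
  r2 <- outer(xs, xs, function(a, b) sqrt(a^2 + b^2))
  u <- ifelse(r2 < 1, 1, ifelse(r2 == 1, 0.5, 0))
  p <- step_params(h = 1 / 12, dx = dx)
  for (s in 1:24) u <- godunov_step(u, K, K, segs, p, "neumann")
  rr <- seq(0, 8, by = 0.05)
  uref <- reference_radial(rr, ifelse(rr < 1, 1, ifelse(rr == 1, 0.5, 0)),
                           t_end = 2)
  ray <- u[ctr, ctr:n]
  rray <- (0:(n - ctr)) * dx
  expect_lt(max(abs(ray - stats::approx(rr, uref, xout = rray)$y)), 0.02)
})
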