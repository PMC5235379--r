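# Independent reference machinery: a self-contained adaptive Dormand-Prince
# RK45 integrator plus method-of-lines discretizations that deliberately
# share no code path with the production kernels, so agreement between the
# two is evidence rather than tautology.

ode_rk45 <- function(f, y0, t0, t1, rtol = 1e-8, atol = 1e-10, h0 = NULL,
                     max_steps = 2e6) {
  a21 <- 1 / 5
  a31 <- 3 / 40; a32 <- 9 / 40
  a41 <- 44 / 45; a42 <- -56 / 15; a43 <- 32 / 9
  a51 <- 19372 / 6561; a52 <- -25360 / 2187; a53 <- 64448 / 6561
  a54 <- -212 / 729
  a61 <- 9017 / 3168; a62 <- -355 / 33; a63 <- 46732 / 5247
  a64 <- 49 / 176; a65 <- -5103 / 18656
  b1 <- 35 / 384; b3 <- 500 / 1113; b4 <- 125 / 192
  b5 <- -2187 / 6784; b6 <- 11 / 84
  e1 <- 71 / 57600; e3 <- -71 / 16695; e4 <- 71 / 1920
  e5 <- -17253 / 339200; e6 <- 22 / 525; e7 <- -1 / 40

  t <- t0
  y <- y0
  h <- h0 %||% (t1 - t0) / 100
  k1 <- f(t, y)
  steps <- 0L
  while (t < t1) {
    if (steps > max_steps) stop("reference integrator exceeded max_steps")
    h <- min(h, t1 - t)
    k2 <- f(t + h / 5, y + h * a21 * k1)
    k3 <- f(t + 3 * h / 10, y + h * (a31 * k1 + a32 * k2))
    k4 <- f(t + 4 * h / 5, y + h * (a41 * k1 + a42 * k2 + a43 * k3))
    k5 <- f(t + 8 * h / 9, y + h * (a51 * k1 + a52 * k2 + a53 * k3 + a54 * k4))
    k6 <- f(t + h, y + h * (a61 * k1 + a62 * k2 + a63 * k3 + a64 * k4 +
                              a65 * k5))
    ynew <- y + h * (b1 * k1 + b3 * k3 + b4 * k4 + b5 * k5 + b6 * k6)
    k7 <- f(t + h, ynew)
    err <- h * (e1 * k1 + e3 * k3 + e4 * k4 + e5 * k5 + e6 * k6 + e7 * k7)
    sc <- atol + rtol * pmax(abs(y), abs(ynew))
    enorm <- sqrt(mean((err / sc)^2))
    if (!is.finite(enorm)) {
      h <- h / 4
      if (h <= 0 || !is.finite(h)) stop("reference integrator failed")
      next
    }
    if (enorm <= 1) {
      t <- t + h
      y <- ynew
      k1 <- k7
    }
    fac <- if (enorm == 0) 5 else 0.9 * enorm^(-0.2)
    h <- h * min(5, max(0.2, fac))
    steps <- steps + 1L
  }
  y
}

#' Independent 1-D method-of-lines reference solution
#'
#' High-accuracy reference for the 1-D growth-diffusion equation
#' `u_t = c u_xx + lam (1 - u/K) u` on a uniform grid, using second-order
#' central differences (mirror ghosts for Neumann ends, zero ghosts for
#' Dirichlet) and adaptive embedded Runge-Kutta (4)5 time integration. Run it
#' at several times the production resolution and it plays the role of a
#' trusted black-box verifier for the semi-implicit scheme.
#'
#' @param x uniform grid (used for `dx`; length must match `u0`).
#' @param u0 initial profile on `x`.
#' @param c,lam diffusion coefficient and growth rate.
#' @param K capacity (scalar or vector on `x`).
#' @param t_end integration time.
#' @param bc `"neumann"` or `"dirichlet"`.
#' @param rtol,atol integrator tolerances.
#' @return profile at `t_end` on `x`.
#' @export
reference_1d <- function(x, u0, c = 0.5, lam = 1, K = 1, t_end,
                         bc = c("neumann", "dirichlet"),
                         rtol = 1e-8, atol = 1e-10) {
  bc <- match.arg(bc)
  n <- length(x)
  stopifnot(length(u0) == n, n >= 3L)
  dx <- x[2L] - x[1L]
  K <- rep_len(K, n)
  cdx2 <- c / dx^2
  f <- if (bc == "neumann") {
    function(t, u) {
      lap <- c(2 * (u[2L] - u[1L]),
               u[-c(n - 1L, n)] - 2 * u[-c(1L, n)] + u[-c(1L, 2L)],
               2 * (u[n - 1L] - u[n]))
      cdx2 * lap + lam * (1 - u / K) * u
    }
  } else {
    function(t, u) {
      lap <- c(u[2L] - 2 * u[1L],
               u[-c(n - 1L, n)] - 2 * u[-c(1L, n)] + u[-c(1L, 2L)],
               u[n - 1L] - 2 * u[n])
      cdx2 * lap + lam * (1 - u / K) * u
    }
  }
  ode_rk45(f, u0, 0, t_end, rtol = rtol, atol = atol)
}

#' Radially symmetric 2-D reference solution
#'
#' Method-of-lines reference for the rotationally symmetric 2-D problem,
#' `u_t = c (u_rr + u_r / r) + lam (1 - u/K) u` on `r in [0, R]` with
#' symmetry at the origin (`grad u(0) = 0`, where the Laplacian limit is
#' `2 u_rr`) and a zero-flux outer wall. Profiles along any ray of a genuinely
#' 2-D run with a centered radial seed must match this reference.
#'
#' @param r uniform radial grid starting at 0.
#' @param u0 initial radial profile.
#' @inheritParams reference_1d
#' @return radial profile at `t_end`.
#' @export
reference_radial <- function(r, u0, c = 0.5, lam = 1, K = 1, t_end,
                             rtol = 1e-8, atol = 1e-10) {
  n <- length(r)
  stopifnot(length(u0) == n, n >= 3L, abs(r[1L]) < 1e-12)
  dr <- r[2L] - r[1L]
  K <- rep_len(K, n)
  inner <- 2:(n - 1L)
  ri <- r[inner]
  f <- function(t, u) {
    lap <- numeric(n)
    lap[1L] <- 4 * (u[2L] - u[1L]) / dr^2
    lap[inner] <- (u[inner + 1L] - 2 * u[inner] + u[inner - 1L]) / dr^2 +
      (u[inner + 1L] - u[inner - 1L]) / (2 * dr * ri)
    lap[n] <- 2 * (u[n - 1L] - u[n]) / dr^2
    c * lap + lam * (1 - u / K) * u
  }
  ode_rk45(f, u0, 0, t_end, rtol = rtol, atol = atol)
}

#' Closed-form logistic growth solution
#'
#' `u(t) = K u0 e^(lam t) / (K + u0 (e^(lam t) - 1))`, the diffusion-free
#' limit used to validate both the reference integrator and the
#' single-cell solver path.
#'
#' @param u0 initial density.
#' @param t time.
#' @param lam growth rate.
#' @param K capacity.
#' @return density at `t`.
#' @export
logistic_solution <- function(u0, t, lam = 1, K = 1) {
  g <- exp(lam * t)
  K * u0 * g / (K + u0 * (g - 1))
}

#' Front position by level crossing
#'
#' Rightmost downward crossing of `u = level`, located by linear
#' interpolation between grid points.
#'
#' @param x grid coordinates (increasing).
#' @param u profile on `x`.
#' @param level crossing level in `(0, max u)`.
#' @return crossing coordinate, or `NA` if the profile never crosses.
#' @export
front_position <- function(x, u, level = 0.5) {
  above <- u >= level
  if (!any(above) || all(above)) return(NA_real_)
  idx <- which(above[-length(u)] & !above[-1L])
  if (length(idx) == 0L) return(NA_real_)
  i <- max(idx)
  x[i] + (level - u[i]) * (x[i + 1L] - x[i]) / (u[i + 1L] - u[i])
}

#' Estimate the traveling-front speed from a profile trace
#'
#' Tracks the level crossing through a sequence of profiles and fits a
#' straight line to position versus time over the last half of the trace
#' (where the front has settled toward its asymptotic speed).
#'
#' @param times step times.
#' @param profiles matrix with one row per time (or list of profiles).
#' @param x grid coordinates.
#' @param level tracked density level.
#' @return list with `speed`, `residual` (RMS of the linear fit), the fitted
#'   `window`, and the raw `positions`.
#' @export
estimate_front_speed <- function(times, profiles, x, level = 0.5) {
  if (is.list(profiles)) profiles <- do.call(rbind, profiles)
  pos <- vapply(seq_along(times),
                function(n) front_position(x, profiles[n, ], level), 0.0)
  ok <- !is.na(pos)
  if (sum(ok) < 4L) stop("no usable front crossings in the trace")
  times <- times[ok]
  pos <- pos[ok]
  i0 <- ceiling(length(times) / 2)
  window <- i0:length(times)
  fit <- stats::lm(pos[window] ~ times[window])
  list(speed = unname(stats::coef(fit)[2L]),
       residual = sqrt(mean(stats::residuals(fit)^2)),
       window = range(times[window]),
       positions = data.frame(time = times, position = pos))
}

#' Amplification factor of the explicit 2-D Euler diffusion update
#'
#' Brute-force von Neumann analysis: for the explicit update
#' `u <- u + k (Ax + Ay) u`, the Fourier gain at angles `(tx, ty)` is
#' `1 - 2k (2 - cos tx - cos ty)`. Returns the maximum modulus over an angle
#' grid that includes the worst mode `(pi, pi)`.
#'
#' @param k CFL parameter.
#' @param n_theta angles per axis.
#' @return maximum gain modulus.
#' @export
explicit_gain_2d <- function(k, n_theta = 65) {
  theta <- seq(0, pi, length.out = n_theta)
  # bracket is (2 - cos tx - cos ty), worst mode at tx = ty = pi
  s <- outer(-cos(theta), -cos(theta), "+") + 2
  max(abs(1 - 2 * k * s))
}

#' Critical CFL number of the explicit scheme by brute-force scan
#'
#' Scans candidate `k` values and returns the largest whose worst-mode gain
#' does not exceed 1; the analytic answer for the 2-D five-point stencil is
#' `k = 1/4`.
#'
#' @param k_values candidate CFL values (default covers `[0.05, 0.60]` in
#'   steps of 0.01).
#' @param tol slack on the unit circle for rounding.
#' @return the critical `k`.
#' @export
explicit_stability_threshold <- function(k_values = seq(0.05, 0.60, by = 0.01),
                                         tol = 1e-9) {
  gains <- vapply(k_values, explicit_gain_2d, 0.0)
  stable <- k_values[gains <= 1 + tol]
  if (length(stable) == 0L) stop("no stable k in the scanned range")
  max(stable)
}

#' Amplification factor of the split semi-implicit step
#'
#' Fourier gain of the pure-diffusion Godunov-split step (x trapezoidal
#' half-step, y trapezoidal full step, x half-step):
#' `g = ((1 - k sx/4)/(1 + k sx/4))^2 (1 - k sy/2)/(1 + k sy/2)` with
#' `s = 2 - 2 cos theta`. Its modulus never exceeds 1 for any `k > 0`, which
#' is why the scheme runs comfortably at `k ~ 1`.
#'
#' @inheritParams explicit_gain_2d
#' @return maximum gain modulus over the angle grid.
#' @export
split_step_gain <- function(k, n_theta = 65) {
  theta <- seq(0, pi, length.out = n_theta)
  s <- 2 - 2 * cos(theta)
  gx <- (1 - k * s / 4) / (1 + k * s / 4)
  gy <- (1 - k * s / 2) / (1 + k * s / 2)
  max(abs(outer(gx^2, gy)))
}

#' Deterministic synthetic worlds
#'
#' Generates the masks, capacity-frame stacks and suggested site pixels that
#' exercise every part of the pipeline without any external data:
#'
#' * `"corridor"`: a fully habitable `nrows x ncols` strip at constant
#'   capacity — the 1-D testbed for traveling waves and arrival curves.
#' * `"island"`: a rectangular island with a 2-cell water margin.
#' * `"two_islands_bridge"`: two islands separated by water, joined by a
#'   1-pixel-wide land bridge whose capacity is zero in every frame before
#'   `bridge_open_frame` and `K` afterwards (an opening land-bridge
#'   narrative); there is zero land connectivity before the opening frame.
#' * `"archipelago"`: an island collection guaranteed to contain habitable
#'   row/column segments of lengths 1, 2, 3 and > 3 (the short-segment
#'   special cases), plus `seed`-controlled scattered cells.
#'
#' Output is deterministic for a fixed `seed`.
#'
#' @param scenario world type.
#' @param nrows,ncols grid shape.
#' @param K land capacity level.
#' @param frame_times frame schedule on the simulation clock (default
#'   `c(0, t_span)`); `two_islands_bridge` needs at least 3 frames.
#' @param bridge_open_frame index of the first frame with the bridge open.
#' @param seed RNG seed for the archipelago's scattered cells.
#' @param cellsize cell size passed through to the series.
#' @return list with `series` (a [capacity_series()]), `mask` (habitability
#'   of the first frame interval), and `sites` (data frame of suggested
#'   pixels).
#' @export
synthetic_world <- function(scenario = c("corridor", "island",
                                         "two_islands_bridge", "archipelago"),
                            nrows = 1, ncols = 200, K = 1,
                            frame_times = c(0, 1), bridge_open_frame = 3,
                            seed = 0, cellsize = 1) {
  scenario <- match.arg(scenario)
  base <- matrix(0, nrows, ncols)
  sites <- NULL
  frames <- NULL
  if (scenario == "corridor") {
    land <- base + K
    frames <- lapply(frame_times, function(t) land)
    sites <- data.frame(name = c("near", "far"),
                        row = c(max(1L, nrows %/% 2L), max(1L, nrows %/% 2L)),
                        col = c(ceiling(ncols * 0.25), ceiling(ncols * 0.75)))
  } else if (scenario == "island") {
    if (nrows < 5L || ncols < 5L) stop("island world needs at least 5 x 5 cells")
    land <- base
    land[3:(nrows - 2L), 3:(ncols - 2L)] <- K
    frames <- lapply(frame_times, function(t) land)
    sites <- data.frame(name = "center",
                        row = (nrows + 1L) %/% 2L, col = (ncols + 1L) %/% 2L)
  } else if (scenario == "two_islands_bridge") {
    if (nrows < 5L || ncols < 15L) stop("bridge world needs at least 5 x 15 cells")
    if (length(frame_times) < 3L) stop("bridge world needs at least 3 frames")
    if (bridge_open_frame < 2L || bridge_open_frame > length(frame_times)) {
      stop("bridge_open_frame outside the frame schedule")
    }
    third <- ncols %/% 3L
    left_cols <- 2:(third)
    right_cols <- (ncols - third + 1L):(ncols - 1L)
    gap_cols <- (third + 1L):(ncols - third)
    closed <- base
    closed[2:(nrows - 1L), left_cols] <- K
    closed[2:(nrows - 1L), right_cols] <- K
    bridge_row <- (nrows + 1L) %/% 2L
    open <- closed
    open[bridge_row, gap_cols] <- K
    frames <- lapply(seq_along(frame_times), function(i) {
      if (i >= bridge_open_frame) open else closed
    })
    sites <- data.frame(name = c("left", "bridge", "right"),
                        row = bridge_row,
                        col = c(left_cols[2L], gap_cols[ceiling(length(gap_cols) / 2)],
                                right_cols[length(right_cols) - 1L]))
  } else { # archipelago
    if (nrows < 12L || ncols < 16L) stop("archipelago needs at least 12 x 16 cells")
    land <- base
    land[2L, 2L] <- K                               # 1-cell islet
    land[2L, 5:6] <- K                              # 2-cell row segment
    land[2L, 9:11] <- K                             # 3-cell row segment
    land[4:5, 14L] <- K                             # 2-cell column segment
    land[7:9, 2L] <- K                              # 3-cell column segment
    land[7:(nrows - 2L), 5:(ncols - 2L)] <- K      # big island (> 3 both ways)
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    extra <- which(land == 0 & base == 0)
    extra <- sample(extra, size = min(5L, length(extra)))
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    land[extra] <- K
    frames <- lapply(frame_times, function(t) land)
    sites <- data.frame(name = "big", row = nrows - 3L, col = ncols - 3L)
  }
  series <- capacity_series(frame_times, frames, cellsize = cellsize)
  list(series = series,
       mask = interval_mask(series, 1L),
       sites = sites)
}
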