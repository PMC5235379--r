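#' Step parameters for the finite-difference scheme
#'
#' Bundles the time step, grid spacing, diffusion coefficient `c` (so the
#' physical diffusivity is D = 2c), growth rate `lam`, and the derived CFL
#' parameter `k = c * h / dx^2` (which reduces to `h / (2 dx^2)` in the
#' scaled equation with c = 1/2). An explicit integrator would need
#' `k < 1/4`; the semi-implicit scheme is routinely run at `k` of order 1.
#'
#' @param h time step (> 0), in the same time unit as `1/lam`.
#' @param dx grid spacing (> 0), same length unit as `sqrt(c * time)`.
#' @param c diffusion coefficient (>= 0), length^2/time; D = 2c.
#' @param lam logistic growth rate (>= 0), 1/time.
#' @return object of class `kpp_step_params`: list `h`, `dx`, `c`, `lam`, `k`.
#' @export
step_params <- function(h, dx, c = 0.5, lam = 1) {
  if (!(h > 0) || !(dx > 0)) stop("h and dx must be positive")
  if (c < 0 || lam < 0) stop("c and lam must be non-negative")
  structure(list(h = h, dx = dx, c = c, lam = lam, k = c * h / dx^2),
            class = "kpp_step_params")
}

#' @export
print.kpp_step_params <- function(x, ...) {
  cat(sprintf("<kpp_step_params> h=%g dx=%g c=%g lam=%g  (CFL k=%g, lam*h=%g)\n",
              x$h, x$dx, x$c, x$lam, x$k, x$lam * x$h))
  invisible(x)
}

# Action of the 1-D second-difference operator with a ghost-cell policy.
# "none"/"zero": plain (1,-2,1) rows with nothing beyond the ends (the raw
# matrix A); "mirror": u0 = u2 and u_{n+1} = u_{n-1}, giving a zero-flux
# stencil to second order.
apply_A <- function(u, ghost = "none") {
  n <- length(u)
  if (n == 1L) {
    return(if (ghost == "mirror") 0 else -2 * u)
  }
  left_ghost <- if (ghost == "mirror") u[2L] else 0
  right_ghost <- if (ghost == "mirror") u[n - 1L] else 0
  left <- c(left_ghost, u[-n])
  right <- c(u[-1L], right_ghost)
  left - 2 * u + right
}

#' Raw 1-D difference operator
#'
#' Applies the tridiagonal second-difference matrix with rows `(1, -2, 1)`
#' and no ghost values; boundary handling is the caller's business. A length-1
#' vector returns `-2 u`.
#'
#' @param u numeric vector.
#' @return `A %*% u` as a numeric vector.
#' @export
diffusion_operator <- function(u) {
  if (length(u) < 1L) stop("u must have length >= 1")
  apply_A(u, "none")
}

dense_tridiag_solve <- function(sub, diag, super, rhs) {
  n <- length(diag)
  M <- base::diag(diag, n, n)
  if (n > 1L) {
    M[cbind(2:n, 1:(n - 1))] <- sub
    M[cbind(1:(n - 1), 2:n)] <- super
  }
  as.numeric(solve(M, rhs))
}

#' Solve a tridiagonal linear system
#'
#' Thomas elimination without pivoting, justified because every system the
#' scheme assembles has an O(1)-strong diagonal; if a pivot becomes tiny the
#' solver falls back to a dense factorization of the same system.
#'
#' @param sub sub-diagonal, length `n - 1` (ignored when `n = 1`).
#' @param diag main diagonal, length `n`.
#' @param super super-diagonal, length `n - 1` (ignored when `n = 1`).
#' @param rhs right-hand side, length `n`.
#' @return solution vector `x` with `T x = rhs`.
#' @export
solve_tridiagonal <- function(sub, diag, super, rhs) {
  n <- length(diag)
  if (length(rhs) != n) stop("rhs length must match diagonal length")
  scale <- max(abs(diag), abs(sub), abs(super), 1)
  tol <- 1e-12 * scale
  if (n == 1L) {
    if (abs(diag[1]) <= tol) stop("singular tridiagonal system")
    return(rhs[1] / diag[1])
  }
  if (length(sub) != n - 1L || length(super) != n - 1L) {
    stop("sub/super diagonals must have length n - 1")
  }
  cp <- numeric(n - 1L)
  dp <- numeric(n)
  piv <- diag[1]
  if (abs(piv) <= tol) return(dense_tridiag_solve(sub, diag, super, rhs))
  cp[1] <- super[1] / piv
  dp[1] <- rhs[1] / piv
  for (i in 2:n) {
    piv <- diag[i] - sub[i - 1L] * cp[i - 1L]
    if (abs(piv) <= tol) return(dense_tridiag_solve(sub, diag, super, rhs))
    if (i < n) cp[i] <- super[i] / piv
    dp[i] <- (rhs[i] - sub[i - 1L] * dp[i - 1L]) / piv
  }
  x <- numeric(n)
  x[n] <- dp[n]
  if (n > 1L) for (i in (n - 1L):1L) x[i] <- dp[i] - cp[i] * x[i + 1L]
  x
}

clamp_vec <- function(u, K) pmin(pmax(u, 0), K)

check_capacity <- function(K) {
  if (any(!is.finite(K)) || any(K <= 0)) {
    stop("carrying capacity must be positive and finite on habitable cells")
  }
}

#' Explicit Euler predictor for one segment
#'
#' One explicit Euler step of the growth-diffusion update,
#' `uE = u + k A u + lam h (1 - u/K_t) u`, with a boundary-consistent
#' operator action: Neumann segments use mirror ghosts (zero flux to second
#' order), Dirichlet segments use zero ghosts. The Neumann two-cell special
#' case applies the raw 2x2 operator to the old data and then equalizes the
#' two entries. The result is clamped to `[0, K_th]`.
#'
#' @param u segment values at time t (`0 <= u <= K_t`).
#' @param K_t carrying capacity on the segment at time t (positive).
#' @param params a [step_params()].
#' @param bc `"neumann"` or `"dirichlet"`.
#' @param K_th capacity at time t + h used for the clamp (default `K_t`).
#' @return the clamped Euler estimate `uE`.
#' @export
euler_predictor <- function(u, K_t, params, bc = c("neumann", "dirichlet"),
                            K_th = K_t) {
  bc <- match.arg(bc)
  check_capacity(K_t)
  n <- length(u)
  lh <- params$lam * params$h
  if (bc == "neumann" && n == 1L) {
    uE <- u + lh * (1 - u / K_t) * u
  } else if (bc == "neumann" && n == 2L) {
    uE <- u + params$k * apply_A(u, "none") + lh * (1 - u / K_t) * u
    uE <- rep(mean(uE), 2L)
  } else {
    ghost <- if (bc == "neumann") "mirror" else "zero"
    uE <- u + params$k * apply_A(u, ghost) + lh * (1 - u / K_t) * u
  }
  clamp_vec(uE, K_th)
}

# Heun (explicit trapezoid) estimate of the end-adjacent interior values used
# to decouple the 1/3 corner entries of the Neumann system. `weight` is the
# operator weight of the explicit full update this step is consistent with
# (k for the growth step, k/2 for a diffusion half-step); growth terms are
# included only when `growth = TRUE`.
heun_estimate <- function(u, K_t, K_th, params, weight, growth) {
  lh <- params$lam * params$h
  phi <- function(v, K) {
    out <- weight * apply_A(v, "mirror")
    if (growth) out <- out + lh * (1 - v / K) * v
    out
  }
  uE <- u + phi(u, K_t)
  est <- u + 0.5 * (phi(u, K_t) + phi(uE, K_th))
  clamp_vec(est, K_th)
}

#' Semi-implicit trapezoidal step with Dirichlet (zero padding) ends
#'
#' Solves the linearized Crank-Nicolson system
#' `(1 - k/2 A - lam h/2 (1 - uE/K_th)) u_new = u + k/2 A u +
#' lam h/2 (1 - u/K_t) u` on one segment, where the segment is conceptually
#' padded with one zero cell at each end (so the full `(1,-2,1)` stencil acts
#' at the end cells with zero neighbors and only the land cells are updated).
#' The result is clamped to `[0, K_th]`.
#'
#' @param u segment values at time t.
#' @param uE Euler estimate at time t + h (see [euler_predictor()]).
#' @param K_t,K_th capacity on the segment at times t and t + h.
#' @param params a [step_params()].
#' @return updated segment values.
#' @export
trapezoid_step_dirichlet <- function(u, uE, K_t, K_th, params) {
  check_capacity(K_t); check_capacity(K_th)
  n <- length(u)
  k <- params$k
  lh <- params$lam * params$h
  rhs <- u + (k / 2) * apply_A(u, "zero") + (lh / 2) * (1 - u / K_t) * u
  dg <- 1 + k - (lh / 2) * (1 - uE / K_th)
  off <- rep(-k / 2, max(n - 1L, 0L))
  x <- solve_tridiagonal(off, dg, off, rhs)
  clamp_vec(x, K_th)
}

#' Semi-implicit Neumann step on a long segment (n > 3)
#'
#' Assembles the zero-net-flux system whose first and last rows are the
#' second-order one-sided derivative constraints `(1, -4/3, 1/3)` /
#' `(1/3, -4/3, 1)` with zero right-hand side, and whose interior rows are the
#' linearized trapezoidal update. The two 1/3 corner entries (which break the
#' tridiagonal bandwidth) are replaced by explicit Heun estimates of `u[3]`
#' and `u[n-2]` at the new time, moved to the right-hand side
#' (`RHS1 = -(1/3) u3_est`, `RHSn = -(1/3) u[n-2]_est`), so a plain
#' tridiagonal solve applies. Optionally the two end cells are refreshed from
#' the boundary rows after the solve; this makes no discernible difference
#' and is off by default.
#'
#' @inheritParams trapezoid_step_dirichlet
#' @param refresh_ends recompute `u[1]`, `u[n]` from the boundary rows using
#'   the solved interior values.
#' @return updated segment values, clamped to `[0, K_th]`.
#' @export
assemble_neumann_step <- function(u, uE, K_t, K_th, params,
                                  refresh_ends = FALSE) {
  n <- length(u)
  if (n <= 3L) stop("assemble_neumann_step requires n_seg > 3; use short_segment_step")
  check_capacity(K_t); check_capacity(K_th)
  k <- params$k
  lh <- params$lam * params$h
  est <- heun_estimate(u, K_t, K_th, params, weight = k, growth = TRUE)
  int <- 2:(n - 1L)
  dg <- c(1,
          1 + k - (lh / 2) * (1 - uE[int] / K_th[int]),
          1)
  sub <- c(rep(-k / 2, n - 2L), -4 / 3)
  super <- c(-4 / 3, rep(-k / 2, n - 2L))
  rhs <- c(-est[3L] / 3,
           u[int] + (k / 2) * (u[int - 1L] - 2 * u[int] + u[int + 1L]) +
             (lh / 2) * (1 - u[int] / K_t[int]) * u[int],
           -est[n - 2L] / 3)
  x <- solve_tridiagonal(sub, dg, super, rhs)
  if (refresh_ends) {
    x[1L] <- (4 / 3) * x[2L] - x[3L] / 3
    x[n] <- (4 / 3) * x[n - 1L] - x[n - 2L] / 3
  }
  clamp_vec(x, K_th)
}

#' Semi-implicit Neumann step on short segments (n = 1, 2, 3)
#'
#' Zero-flux segments of one, two or three cells carry no usable derivative
#' information, so they get dedicated updates:
#' * `n = 1`: the diffusion operator is dropped and the single cell takes the
#'   semi-implicit logistic update (Euler predictor, then the linearized
#'   trapezoid).
#' * `n = 2`: the raw 2x2 operator acts on the old data; zero net flux then
#'   forces the two entries equal at every stage (the common value is their
#'   mean).
#' * `n = 3`: the bordered system forces `u1 = u2 = u3`; the common value is
#'   `RHS2 / (2 S1 + S2)` with `S1 = -k/2` and
#'   `S2 = 1 + k - lam h/2 (1 - uE2/K_th2)`.
#'
#' All stages are kept non-negative and clamped to the local capacity.
#'
#' @param u segment values at time t (length 1, 2 or 3).
#' @param K_t,K_th capacity at times t and t + h.
#' @param params a [step_params()].
#' @return updated segment values.
#' @export
short_segment_step <- function(u, K_t, K_th, params) {
  n <- length(u)
  if (n > 3L) stop("short_segment_step handles n_seg <= 3 only")
  check_capacity(K_t); check_capacity(K_th)
  k <- params$k
  lh <- params$lam * params$h
  if (n == 1L) {
    uE <- clamp_vec(u + lh * (1 - u / K_t) * u, K_th)
    num <- (1 + (lh / 2) * (1 - u / K_t)) * u
    den <- 1 - (lh / 2) * (1 - uE / K_th)
    return(clamp_vec(num / den, K_th))
  }
  if (n == 2L) {
    uE <- u + k * apply_A(u, "none") + lh * (1 - u / K_t) * u
    uE <- clamp_vec(rep(mean(uE), 2L), K_th)
    rhs <- u + (k / 2) * apply_A(u, "none") + (lh / 2) * (1 - u / K_t) * u
    dg <- 1 + k - (lh / 2) * (1 - uE / K_th)
    x <- dense_tridiag_solve(-k / 2, dg, -k / 2, rhs)
    return(clamp_vec(rep(mean(x), 2L), K_th))
  }
  # n == 3: all entries equal RHS2 / (2 S1 + S2)
  uE <- euler_predictor(u, K_t, params, bc = "neumann", K_th = K_th)
  S1 <- -k / 2
  S2 <- 1 + k - (lh / 2) * (1 - uE[2L] / K_th[2L])
  rhs2 <- u[2L] + (k / 2) * (u[1L] - 2 * u[2L] + u[3L]) +
    (lh / 2) * (1 - u[2L] / K_t[2L]) * u[2L]
  val <- rhs2 / (2 * S1 + S2)
  clamp_vec(rep(val, 3L), K_th)
}

# Trapezoidal pure-diffusion update of one segment:
# (1 - kw A) u_new = (1 + kw A) u, with kw = k/4 for a half-step (or k/2 for
# two fused half-steps). Neumann boundary rows follow the same one-sided
# pattern as the growth step, with a diffusion-only Heun estimate feeding the
# corner terms; short Neumann segments use their special cases.
diffusion_segment <- function(u, K_clamp, params, bc, kw) {
  n <- length(u)
  if (bc == "dirichlet") {
    dg <- rep(1 + 2 * kw, n)
    off <- rep(-kw, max(n - 1L, 0L))
    rhs <- u + kw * apply_A(u, "zero")
    return(clamp_vec(solve_tridiagonal(off, dg, off, rhs), K_clamp))
  }
  if (n == 1L) return(clamp_vec(u, K_clamp))
  if (n == 2L) {
    rhs <- u + kw * apply_A(u, "none")
    x <- dense_tridiag_solve(-kw, rep(1 + 2 * kw, 2L), -kw, rhs)
    return(clamp_vec(rep(mean(x), 2L), K_clamp))
  }
  if (n == 3L) {
    # bordered system with S1 = -kw, S2 = 1 + 2 kw; 2 S1 + S2 = 1
    rhs2 <- u[2L] + kw * (u[1L] - 2 * u[2L] + u[3L])
    return(clamp_vec(rep(rhs2, 3L), K_clamp))
  }
  est <- heun_estimate(u, K_clamp, K_clamp, params, weight = 2 * kw,
                       growth = FALSE)
  int <- 2:(n - 1L)
  dg <- c(1, rep(1 + 2 * kw, n - 2L), 1)
  sub <- c(rep(-kw, n - 2L), -4 / 3)
  super <- c(-4 / 3, rep(-kw, n - 2L))
  rhs <- c(-est[3L] / 3,
           u[int] + kw * (u[int - 1L] - 2 * u[int] + u[int + 1L]),
           -est[n - 2L] / 3)
  clamp_vec(solve_tridiagonal(sub, dg, super, rhs), K_clamp)
}

# Full 1-D semi-implicit growth-diffusion step on one segment (predictor +
# linearized trapezoid) with the requested boundary treatment. This is the
# y-direction workhorse and also serves as the unsplit 1-D scheme.
growth_segment <- function(u, K_t, K_th, params, bc, uE = NULL,
                           refresh_ends = FALSE) {
  n <- length(u)
  if (bc == "neumann" && n <= 3L) {
    return(short_segment_step(u, K_t, K_th, params))
  }
  if (is.null(uE)) uE <- euler_predictor(u, K_t, params, bc = bc, K_th = K_th)
  if (bc == "dirichlet") {
    trapezoid_step_dirichlet(u, uE, K_t, K_th, params)
  } else {
    assemble_neumann_step(u, uE, K_t, K_th, params,
                          refresh_ends = refresh_ends)
  }
}

#' One full 1-D semi-implicit step
#'
#' Convenience wrapper advancing a single 1-D profile by one step of the
#' unsplit scheme: explicit Euler predictor, then the linearized trapezoidal
#' solve, with Dirichlet or Neumann ends and stage clamping. Capacities may
#' be scalars (recycled).
#'
#' @param u profile at time t.
#' @param params a [step_params()].
#' @param K_t,K_th capacity at times t and t + h (scalar or vector).
#' @param bc boundary mode.
#' @param refresh_ends see [assemble_neumann_step()].
#' @return profile at time t + h.
#' @export
kpp_step_1d <- function(u, params, K_t = 1, K_th = K_t,
                        bc = c("neumann", "dirichlet"),
                        refresh_ends = FALSE) {
  bc <- match.arg(bc)
  K_t <- rep_len(K_t, length(u))
  K_th <- rep_len(K_th, length(u))
  growth_segment(u, K_t, K_th, params, bc, refresh_ends = refresh_ends)
}
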