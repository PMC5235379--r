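#' Clamp a field to the local carrying capacity
#'
#' Elementwise `max(0, min(K, u))`. Water cells (K = 0) are forced to zero.
#' This regularization is applied after every named stage of the split step.
#'
#' @param u numeric matrix.
#' @param K capacity matrix of the same shape.
#' @return clamped matrix.
#' @export
clamp_to_capacity <- function(u, K) {
  if (!all(dim(u) == dim(K))) stop("shape mismatch between field and capacity")
  pmin(pmax(u, 0), K)
}

#' Trapezoidal pure-diffusion half-step in the x direction
#'
#' Advances every row segment by the half-weighted trapezoid
#' `(1 - k/4 Ax) u_new = (1 + k/4 Ax) u` (weights `k/2` when two adjacent
#' half-steps are fused into one full step), clamps to `[0, K_clamp]`, and
#' leaves all non-habitable cells untouched. A Neumann half-step alone is
#' only determined up to a constant (the heat equation with zero-flux ends);
#' uniqueness over a full step comes from the logistic y stage, so half-steps
#' are only ever taken as part of [godunov_step()].
#'
#' @param u field matrix (rows x cols, row 1 = bottom).
#' @param K_clamp capacity matrix used for the stage clamp.
#' @param segs a [segment_mask()] index.
#' @param params a [step_params()].
#' @param bc `"neumann"` or `"dirichlet"`.
#' @param fused take a full-weight x step (two fused half-steps).
#' @return updated field.
#' @export
diffusion_half_step_x <- function(u, K_clamp, segs, params,
                                  bc = c("neumann", "dirichlet"),
                                  fused = FALSE) {
  bc <- match.arg(bc)
  if (is.null(segs$row_segs)) stop("missing segmentation")
  kw <- if (fused) params$k / 2 else params$k / 4
  for (j in seq_len(segs$nrows)) {
    sg <- segs$row_segs[[j]]
    if (nrow(sg) == 0L) next
    for (s in seq_len(nrow(sg))) {
      idx <- sg[s, 1L]:sg[s, 2L]
      u[j, idx] <- diffusion_segment(u[j, idx], K_clamp[j, idx], params, bc, kw)
    }
  }
  u
}

#' Explicit y-direction predictor
#'
#' Column-wise Euler estimate `uE = u* + k Ay u* + lam h (1 - u*/K_t) u*`
#' (full CFL weight, as the scheme prescribes), clamped to `[0, K_th]`.
#' Cells outside the habitable set keep value zero.
#'
#' @param u_star field after the first x half-step.
#' @param K_t,K_th capacity at times t and t + h.
#' @inheritParams diffusion_half_step_x
#' @return the Euler estimate field.
#' @export
predictor_y <- function(u_star, K_t, K_th, segs, params,
                        bc = c("neumann", "dirichlet")) {
  bc <- match.arg(bc)
  uE <- matrix(0, nrow = nrow(u_star), ncol = ncol(u_star))
  singles <- integer(0)
  for (i in seq_len(segs$ncols)) {
    sg <- segs$col_segs[[i]]
    if (nrow(sg) == 0L) next
    for (s in seq_len(nrow(sg))) {
      if (bc == "neumann" && sg[s, 1L] == sg[s, 2L]) {
        singles <- c(singles, (i - 1L) * nrow(u_star) + sg[s, 1L])
        next
      }
      idx <- sg[s, 1L]:sg[s, 2L]
      uE[idx, i] <- euler_predictor(u_star[idx, i], K_t[idx, i], params,
                                    bc = bc, K_th = K_th[idx, i])
    }
  }
  if (length(singles) > 0L) {
    # vectorized n = 1 path: logistic-only Euler estimate
    lh <- params$lam * params$h
    v <- u_star[singles]
    est <- v + lh * (1 - v / K_t[singles]) * v
    uE[singles] <- pmin(pmax(est, 0), K_th[singles])
  }
  uE
}

#' Semi-implicit y step
#'
#' Column-wise linearized trapezoidal solve
#' `(1 - k/2 Ay - lam h/2 (1 - uE/K_th)) u** =
#'  (1 + k/2 Ay + lam h/2 (1 - u*/K_t)) u*`,
#' dispatched per segment to the Dirichlet solve, the long-segment Neumann
#' assembly, or the short-segment special cases; clamped to `[0, K_th]`.
#'
#' @param u_star field after the first x half-step.
#' @param uE predictor field from [predictor_y()] (used for `n_seg > 3`;
#'   short Neumann segments recompute their own internal estimate).
#' @inheritParams predictor_y
#' @return updated field `u**`.
#' @export
implicit_y <- function(u_star, uE, K_t, K_th, segs, params,
                       bc = c("neumann", "dirichlet")) {
  bc <- match.arg(bc)
  singles <- integer(0)
  for (i in seq_len(segs$ncols)) {
    sg <- segs$col_segs[[i]]
    if (nrow(sg) == 0L) next
    for (s in seq_len(nrow(sg))) {
      if (bc == "neumann" && sg[s, 1L] == sg[s, 2L]) {
        singles <- c(singles, (i - 1L) * nrow(u_star) + sg[s, 1L])
        next
      }
      idx <- sg[s, 1L]:sg[s, 2L]
      u_star[idx, i] <- growth_segment(u_star[idx, i], K_t[idx, i],
                                       K_th[idx, i], params, bc,
                                       uE = uE[idx, i])
    }
  }
  if (length(singles) > 0L) {
    # vectorized n = 1 path: semi-implicit logistic, same formulas as
    # short_segment_step
    lh <- params$lam * params$h
    v <- u_star[singles]
    Kt <- K_t[singles]
    Kth <- K_th[singles]
    vE <- pmin(pmax(v + lh * (1 - v / Kt) * v, 0), Kth)
    vn <- (1 + (lh / 2) * (1 - v / Kt)) * v / (1 - (lh / 2) * (1 - vE / Kth))
    u_star[singles] <- pmin(pmax(vn, 0), Kth)
  }
  u_star
}

#' One full Godunov-split step
#'
#' Advances the field by one time step `h` via the split sequence: x
#' diffusion half-step, explicit y predictor, semi-implicit y step with
#' growth, x diffusion half-step — with each stage clamped to the capacity of
#' its target time (`u*` to `K_t`; `uE`, `u**` and the final field to
#' `K_th`). Only habitable (segment) cells change.
#'
#' @param u field at time t (matrix; zero off the habitable set).
#' @param K_t capacity field at time t (positive on habitable cells).
#' @param K_th capacity field at time t + h.
#' @param segs a [segment_mask()] index.
#' @param params a [step_params()].
#' @param bc boundary mode.
#' @param first_half take the leading x half-step (skipped when the previous
#'   step already took a fused trailing step).
#' @param last_half `"half"` for the plain trailing half-step, `"fused"` to
#'   take a full-weight trailing x step (absorbing the next step's leading
#'   half), `"none"` to skip it.
#' @return field at time t + h.
#' @export
godunov_step <- function(u, K_t, K_th, segs, params,
                         bc = c("neumann", "dirichlet"),
                         first_half = TRUE, last_half = c("half", "fused", "none")) {
  bc <- match.arg(bc)
  last_half <- match.arg(last_half)
  if (!all(dim(u) == dim(K_t)) || !all(dim(u) == dim(K_th))) {
    stop("grid mismatch between field and capacity frames")
  }
  if (first_half) {
    u <- diffusion_half_step_x(u, K_t, segs, params, bc)
  }
  uE <- predictor_y(u, K_t, K_th, segs, params, bc)
  u <- implicit_y(u, uE, K_t, K_th, segs, params, bc)
  if (last_half != "none") {
    u <- diffusion_half_step_x(u, K_th, segs, params, bc,
                               fused = (last_half == "fused"))
  }
  u
}
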