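# Shared fixtures, built in code at test time.

# Cell-average sampling of the unit indicator |x| < 1: cells centered exactly
# on the jump take 1/2, so coarse and fine grids represent the same initial
# mass (see the methods vignette).
indicator_cells <- function(x) {
  ifelse(abs(x) < 1, 1, ifelse(abs(x) == 1, 0.5, 0))
}

# Advance a 1-D profile n steps with the unsplit kernel.
advance_1d <- function(u, params, n_steps, K = 1, bc = "neumann") {
  for (s in seq_len(n_steps)) u <- kpp_step_1d(u, params, K_t = K, bc = bc)
  u
}

# Rectangular island (2-cell water margin) whose habitable segments are all
# longer than 3 cells: the clean testbed for exact Neumann fixed points.
rect_island <- function(nrows, ncols, K = 1) {
  w <- synthetic_world("island", nrows = nrows, ncols = ncols, K = K,
                       frame_times = c(0, 1e9))
  list(mask = w$mask, K = ifelse(w$mask, K, 0), segs = segment_mask(w$mask),
       series = w$series)
}

# Dense solve of the uncorrected bandwidth-5 Neumann system (corner 1/3
# entries kept): the brute-force oracle for assemble_neumann_step.
dense_neumann_solve <- function(u, uE, K_t, K_th, params) {
  n <- length(u)
  k <- params$k
  lh <- params$lam * params$h
  M <- matrix(0, n, n)
  M[1, 1:3] <- c(1, -4 / 3, 1 / 3)
  M[n, (n - 2):n] <- c(1 / 3, -4 / 3, 1)
  rhs <- numeric(n)
  for (j in 2:(n - 1)) {
    M[j, j - 1] <- -k / 2
    M[j, j] <- 1 + k - (lh / 2) * (1 - uE[j] / K_th[j])
    M[j, j + 1] <- -k / 2
    rhs[j] <- u[j] + (k / 2) * (u[j - 1] - 2 * u[j] + u[j + 1]) +
      (lh / 2) * (1 - u[j] / K_t[j]) * u[j]
  }
  pmin(pmax(solve(M, rhs), 0), K_th)
}

# The bridge world used across pipeline tests: two islands, 1-pixel bridge
# habitable from t = 400 (capacity ramping 0 -> K over [400, 800]).
bridge_world <- function() {
  synthetic_world("two_islands_bridge", nrows = 7, ncols = 24, K = 1,
                  frame_times = c(0, 400, 800, 1600), bridge_open_frame = 3)
}

bridge_config <- function(series, t_start = NULL, t_end = NULL) {
  kpp_config(series, r = 0.02, D = 2, dx = 1, h = 1,
             t_start = t_start, t_end = t_end,
             seed = list(center = c(4, 3), sigma_px = 2, peak_fraction = 0.9))
}
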