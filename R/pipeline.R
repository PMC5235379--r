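#' Build step parameters from physical growth/diffusion inputs
#'
#' Converts the physical growth rate `r` (1/yr) and diffusion coefficient `D`
#' (km^2/yr, `D = 2c`) plus the grid spacing and time step into the scheme's
#' step parameters, and attaches the standard diagnostics: the scaled step
#' `lambda_h = r h`, the scaled spacing `dx_scaled = sqrt(r/D) dx`, and the
#' asymptotic traveling-wave speed `2 sqrt(r D)` (km/yr).
#'
#' @param r logistic growth rate (> 0), 1/yr.
#' @param D diffusion coefficient (> 0), km^2/yr.
#' @param dx_km grid spacing in km.
#' @param h_yr time step in years.
#' @return a [step_params()] with extra fields `lambda_h`, `dx_scaled`,
#'   `wave_speed`.
#' @export
nondimensionalize <- function(r, D, dx_km, h_yr) {
  if (!(r > 0) || !(D > 0) || !(dx_km > 0) || !(h_yr > 0)) {
    stop("r, D, dx_km and h_yr must all be positive")
  }
  p <- step_params(h = h_yr, dx = dx_km, c = D / 2, lam = r)
  p$lambda_h <- r * h_yr
  p$dx_scaled <- sqrt(r / D) * dx_km
  p$wave_speed <- 2 * sqrt(r * D)
  p
}

#' Gaussian seed population
#'
#' Initial field `u0(x) = peak_fraction * K(center) * exp(-d^2 / (2 sigma^2))`
#' with `d` the pixel distance to the center, clamped to `[0, K0]` and zero
#' on water.
#'
#' @param K0 capacity matrix at the start time.
#' @param mask habitability mask matrix.
#' @param center `c(row, col)` of the seed peak (must be habitable).
#' @param sigma_px Gaussian width in pixels (> 0).
#' @param peak_fraction peak height as a fraction of the local capacity.
#' @return seed field matrix.
#' @export
gaussian_seed <- function(K0, mask, center, sigma_px = 3, peak_fraction = 1) {
  if (!(sigma_px > 0)) stop("sigma_px must be positive")
  center <- as.integer(center)
  if (!mask[center[1L], center[2L]]) stop("seed center lies on water")
  rows <- matrix(seq_len(nrow(K0)), nrow(K0), ncol(K0))
  cols <- matrix(seq_len(ncol(K0)), nrow(K0), ncol(K0), byrow = TRUE)
  d2 <- (rows - center[1L])^2 + (cols - center[2L])^2
  u0 <- peak_fraction * K0[center[1L], center[2L]] * exp(-d2 / (2 * sigma_px^2))
  u0[!mask] <- 0
  clamp_to_capacity(u0, ifelse(mask, K0, 0))
}

#' Simulation configuration
#'
#' Collects everything one dispersal run needs. Times are on the series'
#' forward simulation clock (years); if the series carries an `anchor_kya`
#' attribute (see [load_frame_manifest()]) results can also be reported in
#' kilo-years before present.
#'
#' @param series a [capacity_series()].
#' @param r,D growth rate (1/yr) and diffusion coefficient (km^2/yr).
#' @param dx cell size (km); defaults to the series' `cellsize`.
#' @param h requested time step (yr); the actual step divides the simulated
#'   span evenly and never exceeds `h`.
#' @param bc boundary mode, `"neumann"` (default) or `"dirichlet"`.
#' @param ccfrac arrival threshold as a fraction of local capacity (0, 1).
#' @param t_start,t_end simulated span on the simulation clock.
#' @param seed list `(center = c(row, col), sigma_px, peak_fraction)` for a
#'   Gaussian seed, or `NULL` when `u0` is given.
#' @param u0 explicit initial field matrix (overrides `seed`).
#' @param combine_half_steps fuse the trailing x half-step of each step with
#'   the leading half-step of the next (identical to O(h^2), fewer solves).
#' @param trace_every store a copy of the field every this many steps
#'   (0 = no trace).
#' @param snapshot_times simulation times at which to keep snapshots.
#' @param k_floor_frac division guard: habitable-cell capacity is floored at
#'   `k_floor_frac * max(K)` before entering the kernels.
#' @return object of class `kpp_config`.
#' @export
kpp_config <- function(series, r = 1, D = 1, dx = NULL, h,
                       bc = c("neumann", "dirichlet"), ccfrac = 0.1,
                       t_start = NULL, t_end = NULL, seed = NULL, u0 = NULL,
                       combine_half_steps = FALSE, trace_every = 0,
                       snapshot_times = NULL, k_floor_frac = 1e-6) {
  bc <- match.arg(bc)
  stopifnot(inherits(series, "kpp_capacity_series"))
  if (!(ccfrac > 0 && ccfrac < 1)) stop("ccfrac must lie in (0, 1)")
  t_start <- t_start %||% series$times[1L]
  t_end <- t_end %||% series$times[length(series$times)]
  if (!(t_end > t_start)) stop("t_end must exceed t_start")
  if (t_start < series$times[1L] || t_end > series$times[length(series$times)]) {
    stop("frames do not cover the simulated span")
  }
  if (is.null(seed) && is.null(u0)) stop("provide a seed spec or an initial field u0")
  structure(list(series = series, r = r, D = D,
                 dx = dx %||% series$cellsize, h = h, bc = bc,
                 ccfrac = ccfrac, t_start = t_start, t_end = t_end,
                 seed = seed, u0 = u0,
                 combine_half_steps = isTRUE(combine_half_steps),
                 trace_every = trace_every,
                 snapshot_times = snapshot_times,
                 k_floor_frac = k_floor_frac,
                 anchor_kya = attr(series, "anchor_kya")),
            class = "kpp_config")
}

# Capacity as seen by the kernels: floored on habitable cells (division
# guard), exactly zero off the mask.
effective_capacity <- function(K, mask, floor) {
  out <- pmax(K, floor)
  out[!mask] <- 0
  out
}

#' Run a dispersal simulation
#'
#' Advances [godunov_step()] from `t_start` to `t_end`, interpolating the
#' capacity per step via [capacity_at()], resegmenting (and carrying the
#' population across coastline changes) whenever the frame interval changes,
#' and recording per-pixel first-arrival times online: a pixel has *arrived*
#' the first time its density reaches `ccfrac` of the local (interpolated)
#' capacity, with no sub-step interpolation. Deterministic given the
#' configuration.
#'
#' @param config a [kpp_config()].
#' @return object of class `kpp_result`: list with the final field `u`, final
#'   `time`, `arrivals` (matrix of first-arrival simulation times, `NA` where
#'   the wave never arrived), `diagnostics` (per-step max density and total
#'   mass), optional `trace` (`times` + list of fields) and `snapshots`, the
#'   actual step `h_eff`, and the `config`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "kpp_config"))
  series <- config$series
  span <- config$t_end - config$t_start
  n_steps <- max(1L, as.integer(ceiling(span / config$h - 1e-9)))
  h_eff <- span / n_steps
  params <- nondimensionalize(config$r, config$D, config$dx, h_eff)
  if (params$k > 1.25) {
    warning(sprintf(paste0("CFL k = %.3g exceeds 1.25: the explicit predictor ",
                           "can lose positivity and pin fronts; reduce h"),
                    params$k))
  }
  floor_K <- config$k_floor_frac * max(vapply(series$frames, max, 1.0))

  t <- config$t_start
  iv <- series_interval(series, t)
  mask <- interval_mask(series, iv)
  segs <- segment_mask(mask)
  K_t <- effective_capacity(capacity_at(series, t), mask, floor_K)

  if (!is.null(config$u0)) {
    u <- as.matrix(config$u0)
    if (!all(dim(u) == dim(K_t))) stop("u0 shape does not match the frames")
    u[!mask] <- 0
    u <- clamp_to_capacity(u, K_t)
  } else {
    u <- gaussian_seed(K_t, mask, config$seed$center,
                       config$seed$sigma_px %||% 3,
                       config$seed$peak_fraction %||% 1)
  }

  arrivals <- matrix(NA_real_, nrow(u), ncol(u))
  arrivals[mask & u >= config$ccfrac * K_t] <- t

  trace <- NULL
  if (config$trace_every > 0) {
    trace <- list(times = t, fields = list(u))
  }
  snapshots <- list()
  diag_time <- numeric(n_steps + 1L)
  diag_max <- numeric(n_steps + 1L)
  diag_mass <- numeric(n_steps + 1L)
  diag_iv <- integer(n_steps + 1L)
  diag_time[1L] <- t
  diag_max[1L] <- max(u)
  diag_mass[1L] <- sum(u)
  diag_iv[1L] <- iv

  combine <- config$combine_half_steps
  for (s in seq_len(n_steps)) {
    iv_now <- series_interval(series, t)
    if (iv_now != iv) {
      new_mask <- interval_mask(series, iv_now)
      u <- apply_mask_transition(u, mask, new_mask)
      mask <- new_mask
      segs <- segment_mask(mask)
      iv <- iv_now
    }
    t_next <- config$t_start + s * h_eff
    K_t <- effective_capacity(capacity_at(series, t), mask, floor_K)
    K_th <- effective_capacity(capacity_at(series, t_next), mask, floor_K)
    first_half <- (s == 1L || !combine)
    last_half <- if (!combine) "half" else if (s < n_steps) "fused" else "half"
    u <- godunov_step(u, K_t, K_th, segs, params, bc = config$bc,
                      first_half = first_half, last_half = last_half)
    if (any(!is.finite(u))) {
      stop(sprintf("numerical failure (non-finite state) at step %d, t = %g",
                   s, t_next))
    }
    t <- t_next
    hit <- is.na(arrivals) & mask & u >= config$ccfrac * K_th
    arrivals[hit] <- t
    diag_time[s + 1L] <- t
    diag_max[s + 1L] <- max(u)
    diag_mass[s + 1L] <- sum(u)
    diag_iv[s + 1L] <- iv
    if (config$trace_every > 0 && s %% config$trace_every == 0L) {
      trace$times <- c(trace$times, t)
      trace$fields <- c(trace$fields, list(u))
    }
    if (!is.null(config$snapshot_times) &&
        any(abs(config$snapshot_times - t) < h_eff / 2)) {
      snapshots[[sprintf("t%g", t)]] <- u
    }
  }

  diagnostics <- data.frame(step = 0:n_steps, time = diag_time,
                            max_u = diag_max, mass = diag_mass,
                            interval = diag_iv)
  structure(list(u = u, time = t, arrivals = arrivals, mask = mask,
                 diagnostics = diagnostics, trace = trace,
                 snapshots = snapshots, h_eff = h_eff, params = params,
                 config = config),
            class = "kpp_result")
}

#' @export
print.kpp_result <- function(x, ...) {
  cat(sprintf("<kpp_result> t = %g (h_eff = %g), max u = %.4g, %d/%d pixels arrived\n",
              x$time, x$h_eff, max(x$u), sum(!is.na(x$arrivals)),
              sum(x$mask)))
  invisible(x)
}

sim_to_kya <- function(t_sim, anchor_kya) anchor_kya - t_sim / 1000

#' First-arrival time at a site
#'
#' Reads the arrival map of a [run_simulation()] result at one pixel, or — if
#' a `ccfrac` different from the run's is requested and the run kept a full
#' trace — rescans the trace for the first time the density reaches
#' `ccfrac * K(x, t)` at that pixel. Arrival is the first recorded discrete
#' time satisfying the threshold; `NA` means the wave never arrived.
#'
#' @param result a `kpp_result`.
#' @param pixel `c(row, col)`.
#' @param ccfrac threshold fraction; default: the run's own.
#' @param units `"sim"` (simulation years) or `"kya"` (requires an anchored
#'   series).
#' @return scalar time or `NA`.
#' @export
arrival_time <- function(result, pixel, ccfrac = NULL,
                         units = c("sim", "kya")) {
  units <- match.arg(units)
  pixel <- as.integer(pixel)
  cfg <- result$config
  if (is.null(ccfrac) || isTRUE(all.equal(ccfrac, cfg$ccfrac))) {
    t_arr <- result$arrivals[pixel[1L], pixel[2L]]
  } else {
    if (is.null(result$trace)) {
      stop("re-thresholding needs a run with trace_every = 1")
    }
    series <- cfg$series
    floor_K <- cfg$k_floor_frac * max(vapply(series$frames, max, 1.0))
    t_arr <- NA_real_
    for (n in seq_along(result$trace$times)) {
      tt <- result$trace$times[n]
      iv <- series_interval(series, tt)
      msk <- interval_mask(series, iv)
      if (!msk[pixel[1L], pixel[2L]]) next
      K <- effective_capacity(capacity_at(series, tt), msk, floor_K)
      if (result$trace$fields[[n]][pixel[1L], pixel[2L]] >=
          ccfrac * K[pixel[1L], pixel[2L]]) {
        t_arr <- tt
        break
      }
    }
  }
  if (units == "kya") {
    if (is.null(cfg$anchor_kya)) stop("series carries no kya anchor")
    t_arr <- sim_to_kya(t_arr, cfg$anchor_kya)
  }
  t_arr
}

#' RMS misfit between simulated and target arrival times
#'
#' `sqrt(mean((sim - arch)^2))`, which for two sites reduces to the
#' half-sum-of-squares form used to calibrate growth and diffusion against
#' the two reference sites. A missing simulated arrival is penalized with
#' `+Inf`.
#'
#' @param sim simulated arrival times (may contain `NA` = never arrived).
#' @param arch target (archaeological) arrival times, same length.
#' @return non-negative scalar; zero iff the fit is exact.
#' @export
rms_objective <- function(sim, arch) {
  if (length(sim) != length(arch) || length(sim) < 1L) {
    stop("sim and arch must be equal-length, non-empty")
  }
  if (anyNA(sim)) return(Inf)
  sqrt(mean((sim - arch)^2))
}

#' Grid search over growth and diffusion parameters
#'
#' Runs one simulation per `(r, D)` pair, evaluates [rms_objective()] on the
#' supplied sites, and returns the minimizer plus the full RMS surface. Ties
#' are broken deterministically: smallest RMS, then smallest D, then
#' smallest r.
#'
#' @param config a [kpp_config()]; its `r` and `D` are overridden per cell.
#' @param r_values,D_values candidate parameter grids (non-empty).
#' @param sites data frame with columns `row`, `col`, `arch` (target arrival
#'   times, in the `units` requested).
#' @param units units for arrival times fed to the objective.
#' @return list with `best` (list `r`, `D`, `rms`), `surface` (matrix
#'   `length(r_values)` x `length(D_values)`), and `arrivals` (list of
#'   per-cell site arrival vectors).
#' @export
grid_search <- function(config, r_values, D_values, sites,
                        units = c("sim", "kya")) {
  units <- match.arg(units)
  if (length(r_values) < 1L || length(D_values) < 1L) stop("empty parameter grid")
  surface <- matrix(NA_real_, length(r_values), length(D_values),
                    dimnames = list(paste0("r=", r_values),
                                    paste0("D=", D_values)))
  arr_list <- list()
  for (a in seq_along(r_values)) {
    for (b in seq_along(D_values)) {
      cfg <- config
      cfg$r <- r_values[a]
      cfg$D <- D_values[b]
      res <- run_simulation(cfg)
      sim <- vapply(seq_len(nrow(sites)), function(s) {
        arrival_time(res, c(sites$row[s], sites$col[s]), units = units)
      }, 0.0)
      surface[a, b] <- rms_objective(sim, sites$arch)
      arr_list[[paste(a, b, sep = ",")]] <- sim
    }
  }
  if (all(!is.finite(surface))) {
    stop("no parameter combination produced arrivals at all sites")
  }
  cand <- which(surface == min(surface), arr.ind = TRUE)
  ord <- order(D_values[cand[, 2L]], r_values[cand[, 1L]])
  pick <- cand[ord[1L], ]
  list(best = list(r = r_values[pick[1L]], D = D_values[pick[2L]],
                   rms = surface[pick[1L], pick[2L]]),
       surface = surface, arrivals = arr_list)
}
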