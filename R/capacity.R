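#' Classical logistic sigmoid
#'
#' `S(z) = 1 / (1 + exp(-z))`, monotone increasing, with `S(-Inf) = 0` and
#' `S(Inf) = 1` handled exactly.
#'
#' @param z numeric vector (may contain `+/-Inf`).
#' @return values in `[0, 1]`.
#' @export
sigmoid <- function(z) 1 / (1 + exp(-z))

#' Warped time for sigmoid frame interpolation
#'
#' Maps simulation time `t` in a frame interval `[t_L, t_H]` onto the whole
#' real line via
#' `z(t) = (2 DT (t - t_L) - DT^2) / ((t - t_L) (DT - (t - t_L)))^nu`
#' with `DT = t_H - t_L`, so that `S(z(t))` interpolates from exactly 0 at
#' `t_L` to exactly 1 at `t_H`. The endpoints are 0/0 forms and return the
#' analytic limits `-Inf` / `+Inf`. With `nu = 1` the map is invariant under
#' rescaling all times by a common factor, and every time-derivative of
#' `S(z(t))` vanishes at both endpoints. Exponents below 1/2 give the
#' interpolant extra inflection points and are rejected.
#'
#' @param t numeric vector of times inside `[t_L, t_H]`.
#' @param t_L,t_H interval endpoints (`t_H > t_L`).
#' @param nu warp exponent (`>= 1/2`; default 1).
#' @return `z(t)` on the extended reals.
#' @export
warped_time <- function(t, t_L, t_H, nu = 1) {
  if (!(t_H > t_L)) stop("t_H must exceed t_L")
  if (nu < 0.5) stop("nu must be >= 1/2")
  if (any(t < t_L | t > t_H)) stop("t outside [t_L, t_H]")
  DT <- t_H - t_L
  s <- t - t_L
  z <- ifelse(s == 0, -Inf,
              ifelse(s == DT, Inf,
                     (2 * DT * s - DT^2) / (s * (DT - s))^nu))
  z
}

#' Ordered carrying-capacity frame series
#'
#' Holds an ordered stack of capacity frames on a common grid together with
#' the (possibly nonuniform) frame schedule on a forward simulation clock and
#' the sigmoid warp exponent used to interpolate between consecutive frames.
#'
#' @param times strictly increasing numeric vector of frame times
#'   (simulation clock, e.g. years since start).
#' @param frames list of capacity matrices (or [kpp_grid()]s), all the same
#'   shape; water cells are 0 (or `NA`).
#' @param nu sigmoid warp exponent, see [warped_time()].
#' @param water_threshold strict habitability threshold on K.
#' @param cellsize cell size carried along for I/O convenience.
#' @return object of class `kpp_capacity_series`.
#' @export
capacity_series <- function(times, frames, nu = 1, water_threshold = 0,
                            cellsize = 1) {
  if (length(times) != length(frames)) stop("times and frames lengths differ")
  if (length(times) < 2L) stop("need at least two frames")
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  frames <- lapply(frames, function(f) {
    m <- if (inherits(f, "kpp_grid")) f$values else as.matrix(f)
    m[is.na(m)] <- 0
    m
  })
  d <- dim(frames[[1L]])
  if (!all(vapply(frames, function(f) all(dim(f) == d), TRUE))) {
    stop("all frames must share one grid shape")
  }
  if (nu < 0.5) stop("nu must be >= 1/2")
  structure(list(times = as.numeric(times), frames = frames, nu = nu,
                 water_threshold = water_threshold, cellsize = cellsize,
                 nrows = d[1L], ncols = d[2L]),
            class = "kpp_capacity_series")
}

#' @export
print.kpp_capacity_series <- function(x, ...) {
  cat(sprintf("<kpp_capacity_series> %d frames (%d x %d), t in [%g, %g], nu=%g\n",
              length(x$times), x$nrows, x$ncols,
              x$times[1], x$times[length(x$times)], x$nu))
  invisible(x)
}

#' Index of the frame interval bracketing a time
#'
#' Returns `i` such that `times[i] <= t <= times[i+1]`; the upper endpoint of
#' the series belongs to the last interval.
#'
#' @param series a [capacity_series()].
#' @param t time on the simulation clock.
#' @return integer interval index in `1 .. nframes - 1`.
#' @export
series_interval <- function(series, t) {
  tt <- series$times
  if (t < tt[1L] || t > tt[length(tt)]) {
    stop(sprintf("t = %g outside the frame span [%g, %g]",
                 t, tt[1L], tt[length(tt)]))
  }
  min(max(findInterval(t, tt), 1L), length(tt) - 1L)
}

#' Interpolated capacity field at a time
#'
#' Locates the bracketing frame interval and returns the sigmoid homotopy
#' `K(x, t) = K_L(x) (1 - S(z(t))) + K_H(x) S(z(t))` elementwise. At frame
#' times the stored frames are returned exactly.
#'
#' @inheritParams series_interval
#' @return capacity matrix.
#' @export
capacity_at <- function(series, t) {
  i <- series_interval(series, t)
  S <- sigmoid(warped_time(t, series$times[i], series$times[i + 1L],
                           nu = series$nu))
  series$frames[[i]] * (1 - S) + series$frames[[i + 1L]] * S
}

#' Habitability mask of one frame interval
#'
#' A cell is habitable for the whole interval iff `max(K_L, K_H)` exceeds the
#' water threshold, so land that emerges within the interval (an opening
#' bridge) is segmented from the interval start while its interpolated K is
#' still ~0. Resegmentation therefore only happens at frame-interval changes.
#'
#' @param series a [capacity_series()].
#' @param interval interval index (see [series_interval()]).
#' @return logical matrix.
#' @export
interval_mask <- function(series, interval) {
  if (interval < 1L || interval > length(series$times) - 1L) {
    stop("interval index out of range")
  }
  pmax(series$frames[[interval]], series$frames[[interval + 1L]]) >
    series$water_threshold
}

#' Load a capacity series from a frame manifest
#'
#' The manifest is a CSV with columns `time_kya` (kilo-years before present)
#' and `path` (ESRI ASCII grid file, absolute or relative to the manifest).
#' Times are converted once to a forward simulation clock in years,
#' `t_sim = (anchor_kya - time_kya) * 1000`, anchored by default at the
#' earliest (largest-kya) frame.
#'
#' @param path manifest CSV path.
#' @param nu,water_threshold see [capacity_series()].
#' @param anchor_kya clock anchor; defaults to the maximum `time_kya`.
#' @return a [capacity_series()] with attribute `anchor_kya`.
#' @export
load_frame_manifest <- function(path, nu = 1, water_threshold = 0,
                                anchor_kya = NULL) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_kya", "path") %in% names(man))) {
    stop("manifest needs columns time_kya and path")
  }
  man <- man[order(-man$time_kya), , drop = FALSE]
  paths <- ifelse(file.exists(man$path), man$path,
                  file.path(dirname(path), man$path))
  grids <- lapply(paths, read_capacity_grid)
  anchor_kya <- anchor_kya %||% max(man$time_kya)
  times <- (anchor_kya - man$time_kya) * 1000
  series <- capacity_series(times, grids, nu = nu,
                            water_threshold = water_threshold,
                            cellsize = grids[[1L]]$cellsize)
  attr(series, "anchor_kya") <- anchor_kya
  series
}

#' Static two-frame series from a single capacity field
#'
#' Convenience constructor for time-constant worlds: the same frame at the
#' start and end of the requested span.
#'
#' @param K capacity matrix or [kpp_grid()].
#' @param t_start,t_end span on the simulation clock.
#' @param ... passed to [capacity_series()].
#' @return a [capacity_series()].
#' @export
static_series <- function(K, t_start = 0, t_end = 1, ...) {
  capacity_series(c(t_start, t_end), list(K, K), ...)
}
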