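#' Raster grid on a regular square lattice
#'
#' Container for a gridded real-valued field, typically a carrying-capacity
#' map K(x). Cells are square (`cellsize` in km, or any consistent length
#' unit). The value matrix is stored with row 1 at the *bottom* of the map
#' (origin at the lower-left corner), so `values[j, i]` addresses grid row `j`
#' counted south to north and column `i` counted west to east. Missing-data
#' cells are held as `NA` internally and round-trip through
#' `nodata_value` on disk.
#'
#' @param values numeric matrix (rows x cols), non-negative where not `NA`.
#' @param cellsize side length of one (square) cell; must be positive.
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param nodata_value value that encodes missing cells in ESRI ASCII files.
#' @return an object of class `kpp_grid`: a list with fields `ncols`,
#'   `nrows`, `cellsize`, `xll`, `yll`, `nodata_value`, `values`.
#' @seealso [read_capacity_grid()], [write_capacity_grid()],
#'   [habitability_mask()]
#' @export
kpp_grid <- function(values, cellsize = 1, xll = 0, yll = 0,
                     nodata_value = -9999) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("grid must have at least one cell")
  }
  if (!is.numeric(values)) stop("grid values must be numeric")
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0) {
    stop("cellsize must be a single positive number")
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("grid values must be non-negative (water is 0, missing is NA)")
  }
  structure(
    list(ncols = ncol(values), nrows = nrow(values),
         cellsize = as.numeric(cellsize),
         xll = as.numeric(xll), yll = as.numeric(yll),
         nodata_value = as.numeric(nodata_value),
         values = values),
    class = "kpp_grid")
}

#' @export
print.kpp_grid <- function(x, ...) {
  cat(sprintf("<kpp_grid> %d cols x %d rows, cellsize %g, origin (%g, %g)\n",
              x$ncols, x$nrows, x$cellsize, x$xll, x$yll))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  values in [%g, %g], %d NA cells\n",
              rng[1], rng[2], sum(is.na(x$values))))
  invisible(x)
}

#' Read an ESRI ASCII grid file
#'
#' Parses the standard `.asc` header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, optional `NODATA_value`) followed by `nrows` rows
#' of values, top row first as the format prescribes. The returned grid is
#' normalized to origin-lower-left storage (row 1 = southernmost row).
#' Cells equal to the nodata value become `NA`.
#'
#' Only square-cell grids are supported: files carrying separate `dx`/`dy`
#' keys are rejected unless the two are equal.
#'
#' @param path path to an existing `.asc` file.
#' @return a [kpp_grid()].
#' @export
read_capacity_grid <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                   "yllcenter", "cellsize", "nodata_value", "dx", "dy")) {
      if (length(parts) != 2L) stop("malformed header line: ", ln)
      val <- suppressWarnings(as.numeric(parts[2]))
      if (is.na(val)) stop("malformed header value in line: ", ln)
      hdr[[key]] <- val
      n_hdr <- n_hdr + 1L
    } else {
      break
    }
  }
  if (is.null(hdr$ncols) || is.null(hdr$nrows)) {
    stop("malformed ESRI ASCII header: ncols/nrows missing")
  }
  if (!is.null(hdr$dx) || !is.null(hdr$dy)) {
    if (is.null(hdr$dx) || is.null(hdr$dy) || hdr$dx != hdr$dy) {
      stop("non-square cells (dx != dy) are not supported")
    }
    hdr$cellsize <- hdr$dx
  }
  if (is.null(hdr$cellsize)) stop("malformed ESRI ASCII header: cellsize missing")
  if (!is.null(hdr$xllcenter) || !is.null(hdr$yllcenter)) {
    # normalize center registration to corner registration
    hdr$xllcorner <- (hdr$xllcenter %||% 0) - hdr$cellsize / 2
    hdr$yllcorner <- (hdr$yllcenter %||% 0) - hdr$cellsize / 2
  }
  nodata <- hdr$nodata_value %||% -9999
  ncols <- as.integer(hdr$ncols)
  nrows <- as.integer(hdr$nrows)
  body <- lines[(n_hdr + 1L):length(lines)]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(body),
                                                      "[[:space:]]+"))))
  if (anyNA(vals)) stop("non-numeric grid body")
  if (length(vals) != ncols * nrows) {
    stop(sprintf("grid body has %d values, expected %d",
                 length(vals), ncols * nrows))
  }
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  m <- m[nrows:1, , drop = FALSE]        # file is top-first; store bottom-first
  m[m == nodata] <- NA_real_
  kpp_grid(m, cellsize = hdr$cellsize,
           xll = hdr$xllcorner %||% 0, yll = hdr$yllcorner %||% 0,
           nodata_value = nodata)
}

#' Write an ESRI ASCII grid file
#'
#' Inverse of [read_capacity_grid()]: finite values round-trip exactly at the
#' written precision (up to 15 significant digits), `NA` cells are written as
#' the grid's nodata value.
#'
#' @param grid a [kpp_grid()].
#' @param path output file path.
#' @param digits significant digits used for the body.
#' @return `invisible(path)`.
#' @export
write_capacity_grid <- function(grid, path, digits = 15) {
  stopifnot(inherits(grid, "kpp_grid"))
  m <- grid$values
  m[is.na(m)] <- grid$nodata_value
  m <- m[grid$nrows:1, , drop = FALSE]   # emit top row first
  hdr <- c(
    sprintf("ncols %d", grid$ncols),
    sprintf("nrows %d", grid$nrows),
    sprintf("xllcorner %.10g", grid$xll),
    sprintf("yllcorner %.10g", grid$yll),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %.10g", grid$nodata_value))
  body <- apply(m, 1L, function(row) {
    paste(formatC(row, digits = digits, format = "g"), collapse = " ")
  })
  ok <- tryCatch({
    writeLines(c(hdr, body), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write grid to ", path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Habitability mask of a capacity grid
#'
#' A cell is habitable iff its capacity strictly exceeds `water_threshold`
#' (water has K = 0); `NA` (nodata) cells are water.
#'
#' @param grid a [kpp_grid()] or a plain numeric matrix.
#' @param water_threshold strict lower bound for habitability (default 0).
#' @return logical matrix with the grid's shape.
#' @export
habitability_mask <- function(grid, water_threshold = 0) {
  m <- if (inherits(grid, "kpp_grid")) grid$values else as.matrix(grid)
  mask <- !is.na(m) & m > water_threshold
  mask
}

runs_of_true <- function(x) {
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & !is.na(r$values)
  cbind(start = starts[keep], end = ends[keep])
}

#' Row/column segment index of a habitability mask
#'
#' Decomposes the habitable set into maximal runs ("segments") along every
#' grid row and every grid column; these segments are the independent units
#' on which the one-dimensional solvers act. Indices are 1-based inclusive.
#'
#' @param mask logical matrix (see [habitability_mask()]).
#' @return an object of class `kpp_segments`: list with
#'   `row_segs` (per row, a 2-column `start`/`end` matrix of x-runs),
#'   `col_segs` (per column, y-runs), and the mask dimensions.
#' @export
segment_mask <- function(mask) {
  mask <- as.matrix(mask)
  if (!is.logical(mask)) stop("mask must be logical")
  if (length(mask) == 0L) stop("mask is empty")
  row_segs <- lapply(seq_len(nrow(mask)), function(j) runs_of_true(mask[j, ]))
  col_segs <- lapply(seq_len(ncol(mask)), function(i) runs_of_true(mask[, i]))
  structure(list(row_segs = row_segs, col_segs = col_segs,
                 nrows = nrow(mask), ncols = ncol(mask)),
            class = "kpp_segments")
}

#' @export
print.kpp_segments <- function(x, ...) {
  cat(sprintf("<kpp_segments> %d rows (%d x-segments), %d cols (%d y-segments)\n",
              x$nrows, sum(vapply(x$row_segs, nrow, 1L)),
              x$ncols, sum(vapply(x$col_segs, nrow, 1L))))
  invisible(x)
}

#' Carry a population field across a coastline change
#'
#' When the habitable set changes between capacity frames, population on
#' cells that left the habitable set (flooded land) is discarded and newly
#' habitable cells start empty; unchanged cells keep their value. Idempotent
#' for a fixed pair of masks.
#'
#' @param u numeric matrix, the population field (zero off the old mask).
#' @param old,new logical matrices, the previous and the next habitability
#'   masks (same shape as `u`).
#' @return the adjusted field.
#' @export
apply_mask_transition <- function(u, old, new) {
  if (!all(dim(u) == dim(old)) || !all(dim(u) == dim(new))) {
    stop("shape mismatch between field and masks")
  }
  u[!new] <- 0
  u[new & !old] <- 0
  u
}
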