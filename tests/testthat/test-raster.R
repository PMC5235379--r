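test_that("ESRI ASCII grids parse with lower-left origin and nodata flags", {
  f <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 56.0", "NODATA_value -9999",
               "1 0", "2 3"), f)
  g <- read_capacity_grid(f)
  expect_equal(g$cellsize, 56)
  # file rows are top-first, storage is bottom-first
  expect_equal(g$values, matrix(c(2, 1, 3, 0), 2, 2))

  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999",
               "1 -9999", "2 3"), f)
  g2 <- read_capacity_grid(f)
  expect_true(is.na(g2$values[2, 2]))
  expect_equal(sum(is.na(g2$values)), 1L)
})

test_that("write/read round-trips finite values and nodata", {
  set.seed(7)
  m <- matrix(round(runif(30), 6), 5, 6)
  m[2, 3] <- NA
  g <- kpp_grid(m, cellsize = 56, xll = -10, yll = 4.5)
  f <- withr::local_tempfile(fileext = ".asc")
  write_capacity_grid(g, f)
  g2 <- read_capacity_grid(f)
  expect_equal(g2$values, g$values)
  expect_equal(g2$cellsize, g$cellsize)
  expect_equal(g2$xll, g$xll)
  expect_equal(g2$yll, g$yll)
  # idempotent: write the re-read grid again
  f2 <- withr::local_tempfile(fileext = ".asc")
  write_capacity_grid(g2, f2)
  expect_equal(read_capacity_grid(f2)$values, g$values)
})

test_that("malformed and unsupported grids are rejected", {
  f <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "cellsize oops", "1 2", "3 4"), f)
  expect_error(read_capacity_grid(f), "malformed")
  writeLines(c("ncols 2", "nrows 1", "xllcorner 0", "yllcorner 0",
               "dx 1", "dy 2", "1 2"), f)
  expect_error(read_capacity_grid(f), "non-square")
  writeLines(c("ncols 3", "nrows 1", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "1 2"), f)
  expect_error(read_capacity_grid(f), "expected")
  expect_error(kpp_grid(matrix(numeric(0), 0, 0)), "at least one cell")
  expect_error(kpp_grid(matrix(-1, 1, 1)), "non-negative")
})

test_that("habitability mask is strict K > threshold with NA as water", {
  m <- matrix(c(0, 0.5, NA, 2), 2, 2)
  expect_equal(habitability_mask(m), matrix(c(FALSE, TRUE, FALSE, TRUE), 2, 2))
  expect_equal(habitability_mask(m, water_threshold = 0.5),
               matrix(c(FALSE, FALSE, FALSE, TRUE), 2, 2))
})

test_that("segment_mask finds maximal runs by rows and by columns", {
  mask <- matrix(FALSE, 3, 6)
  mask[2, ] <- c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE)
  segs <- segment_mask(mask)
  expect_equal(segs$row_segs[[2]],
               cbind(start = c(2L, 5L), end = c(3L, 5L)))
  expect_equal(nrow(segs$row_segs[[1]]), 0L)
  expect_equal(segs$col_segs[[2]], cbind(start = 2L, end = 2L))

  all_true <- matrix(TRUE, 1, 8)
  expect_equal(segment_mask(all_true)$row_segs[[1]],
               cbind(start = 1L, end = 8L))

  none <- matrix(FALSE, 4, 4)
  segs0 <- segment_mask(none)
  expect_true(all(vapply(segs0$row_segs, nrow, 1L) == 0L))
  expect_true(all(vapply(segs0$col_segs, nrow, 1L) == 0L))
})

test_that("segmentation covers exactly the mask cells (row and column views)", {
  set.seed(11)
  for (trial in 1:20) {
    mask <- matrix(runif(9 * 7) < 0.55, 9, 7)
    segs <- segment_mask(mask)
    row_cells <- matrix(FALSE, 9, 7)
    for (j in 1:9) {
      sg <- segs$row_segs[[j]]
      for (s in seq_len(nrow(sg))) row_cells[j, sg[s, 1]:sg[s, 2]] <- TRUE
    }
    col_cells <- matrix(FALSE, 9, 7)
    for (i in 1:7) {
      sg <- segs$col_segs[[i]]
      for (s in seq_len(nrow(sg))) col_cells[sg[s, 1]:sg[s, 2], i] <- TRUE
    }
    expect_identical(row_cells, mask)
    expect_identical(col_cells, mask)
  }
})

test_that("mask transitions discard flooded population and start new land empty", {
  u <- matrix(c(0.4, 0.2, 0, 0), 2, 2)
  old <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  new <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2)
  out <- apply_mask_transition(u, old, new)
  expect_equal(out, matrix(c(0, 0.2, 0, 0), 2, 2))
  expect_equal(apply_mask_transition(out, old, new), out)  # idempotent
  expect_equal(apply_mask_transition(u, old, old), u)      # identity
  expect_error(apply_mask_transition(u, old, matrix(TRUE, 3, 3)), "mismatch")
})
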