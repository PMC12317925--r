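test_that("an ASCII-grid write/read round trip reproduces the surface exactly", {
  s <- generate_surface("random_field", 12, 15, resolution = 25, seed = 8,
                        nodata_margin = 2L)
  s$crs <- "EPSG:25830"
  path <- file.path(withr::local_tempdir(), "surf.asc")
  write_cost_surface(s, path)
  back <- read_cost_surface(path)
  expect_identical(back$values, s$values)
  expect_identical(is.na(back$values), is.na(s$values))
  expect_equal(back$resolution, s$resolution)
  expect_equal(back$origin, s$origin)
  expect_equal(back$crs, s$crs)
})

test_that("unreadable or malformed rasters are rejected with a reason", {
  expect_error(read_cost_surface("no/such/file.asc"), "no such file")
  td <- withr::local_tempdir()
  bad <- file.path(td, "bad.asc")
  writeLines(c("ncols 3", "nrows banana", "cellsize 1", "1 2 3"), bad)
  expect_error(read_cost_surface(bad), "malformed")
  short <- file.path(td, "short.asc")
  writeLines(c("ncols 3", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "1 2 3"), short)
  expect_error(read_cost_surface(short), "expected")
  badsize <- file.path(td, "badsize.asc")
  writeLines(c("ncols 1", "nrows 1", "xllcorner 0", "yllcorner 0",
               "cellsize -2", "nodata_value -9999", "1"), badsize)
  expect_error(read_cost_surface(badsize), "positive")
})

test_that("the NoData header value is masked on read", {
  td <- withr::local_tempdir()
  p <- file.path(td, "nd.asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 10", "nodata_value -1", "3 -1", "-1 4"), p)
  s <- read_cost_surface(p)
  expect_identical(is.na(s$values), matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2))
})

test_that("Horn slope: flat terrain is 0, unit-gradient planes give the analytic angles", {
  flat <- cost_surface(matrix(120, 6, 6), resolution = 10)
  sl <- slope_from_dem(flat)
  expect_true(all(sl$values[2:5, 2:5] == 0))
  expect_true(all(is.na(sl$values[1, ])))  # border is NoData

  # rise 1 per unit x: 45 degrees
  xc <- (1:8 - 0.5) * 2
  plane_x <- cost_surface(matrix(rep(xc, each = 8), 8, 8), resolution = 2)
  expect_equal(unname(slope_from_dem(plane_x)$values[4, 4]), 45)

  # rise 1 per unit in both x and y: atan(sqrt(2)) = 54.7356...
  yc <- ((8:1) - 0.5) * 2
  plane_xy <- cost_surface(outer(yc, xc, `+`), resolution = 2)
  expect_equal(unname(slope_from_dem(plane_xy)$values[4, 4]),
               atan(sqrt(2)) * 180 / pi, tolerance = 1e-12)

  expect_error(slope_from_dem(cost_surface(matrix(1, 2, 2), 1)), "3 x 3")
})

test_that("slope is invariant under a constant elevation offset and NoData propagates to its window", {
  s <- generate_surface("random_field", 10, 10, resolution = 5, seed = 13)
  s1 <- slope_from_dem(s)
  s2 <- slope_from_dem(cost_surface(s$values + 500, 5, s$origin))
  expect_equal(s1$values, s2$values)
  expect_true(all(s1$values >= 0 & s1$values < 90, na.rm = TRUE))

  h <- s$values; h[5, 5] <- NA
  sl <- slope_from_dem(cost_surface(h, 5, s$origin))
  expect_true(all(is.na(sl$values[4:6, 4:6])))
})

test_that("the tilted plane increases arithmetically along its gradient", {
  s <- generate_surface("tilted_plane", 6, 9, resolution = 10, gradient = c(1, 0))
  for (i in 1:6) expect_equal(unique(round(diff(s$values[i, ]), 10)), 10)
  expect_equal(unique(round(diff(s$values[, 1]), 10)), 0)
})

test_that("each parabolic-valley row attains its minimum on the stated axis", {
  s <- generate_surface("parabolic_valley", 20, 31, resolution = 100,
                        axis_x = 1550)
  jmin <- apply(s$values, 1, which.min)
  expect_true(all(jmin == 16))  # column whose centre is x = 1550
  expect_true(all(diff(s$values[1, 16:31]) > 0))  # quadratic walls rise
})

test_that("the correlated random field is deterministic per seed and leaves the caller's RNG alone", {
  a <- generate_surface("random_field", 15, 15, resolution = 1, seed = 21)
  b <- generate_surface("random_field", 15, 15, resolution = 1, seed = 21)
  c_ <- generate_surface("random_field", 15, 15, resolution = 1, seed = 22)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c_$values))
  expect_true(all(a$values >= 0))

  set.seed(5); r1 <- runif(1)
  set.seed(5); invisible(generate_surface("random_field", 5, 5, seed = 3)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("walks released off-axis converge onto and follow a valley corridor", {
  s <- generate_surface("parabolic_valley", 60, 41, resolution = 1,
                        axis_x = 20.5, curvature = 0.05)
  spec <- neighbourhood_spec("square", 1)
  finals <- vapply(1:5, function(k) {
    w <- run_walk(s, spec, start = c(30.5, 30.5), n_steps = 40, seed = k)
    tail_cells <- w$cells[(nrow(w$cells) - 9):nrow(w$cells), , drop = FALSE]
    mean(abs(cell_centre(tail_cells, spec, s$origin)[, 1] - 20.5))
  }, numeric(1))
  expect_true(all(finals < 1))  # within one lattice cell of the axis
})

test_that("degenerate surface parameters are rejected", {
  expect_error(generate_surface("tilted_plane", 2, 5), "3 x 3")
  expect_error(generate_surface("random_field", 5, 5, correlation = 0), "invalid")
  expect_error(generate_surface("parabolic_valley", 5, 5, curvature = -1), "positive")
  expect_error(generate_surface("tilted_plane", 9, 9, nodata_margin = 4), "interior")
  expect_error(cost_surface(matrix(1, 2, 2), resolution = 0), "positive")
  expect_error(cost_surface(matrix(c(1, Inf), 1, 2), resolution = 1), "finite")
})
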