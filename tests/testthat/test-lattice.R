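test_that("ring offsets match the Moore and hexagonal neighbourhood definitions", {
  sq <- neighbour_offsets("square")
  expect_equal(nrow(sq), 8L)
  expect_false(any(sq[, 1] == 0 & sq[, 2] == 0))
  expect_equal(nrow(unique(sq)), 8L)
  expect_true(all(sq %in% -1:1))

  hx <- neighbour_offsets("hex")
  expect_equal(nrow(hx), 6L)
  expect_setequal(paste(hx[, 1], hx[, 2]),
                  c("1 0", "1 -1", "0 -1", "-1 0", "-1 1", "0 1"))

  expect_error(neighbour_offsets("triangle"), "unknown")
})

test_that("cell centres follow the documented north-up conventions", {
  sq <- neighbourhood_spec("square", 100)
  expect_equal(cell_centre(c(0L, 0L), sq, anchor = c(0, 0)), c(50, -50))
  hx <- neighbourhood_spec("hex", 100)
  expect_equal(cell_centre(c(1L, 0L), hx, anchor = c(0, 0)), c(100, 0))
  expect_equal(cell_centre(c(0L, 1L), hx, anchor = c(0, 0)),
               c(50, -100 * sqrt(3) / 2))
})

test_that("hex neighbour centres are all exactly nsize away; square centres take nsize and nsize*sqrt(2)", {
  set.seed(42)
  for (rep in 1:20) {
    nsize <- runif(1, 0.5, 2000)
    cell <- sample(-50:50, 2)
    hx <- neighbourhood_spec("hex", nsize)
    ctr <- cell_centre(cell, hx)
    d <- apply(neighbour_offsets("hex"), 1, function(o)
      sqrt(sum((cell_centre(cell + o, hx) - ctr)^2)))
    expect_true(all(abs(d - nsize) <= 1e-9 * nsize))

    sq <- neighbourhood_spec("square", nsize)
    ctr <- cell_centre(cell, sq)
    d <- apply(neighbour_offsets("square"), 1, function(o)
      sqrt(sum((cell_centre(cell + o, sq) - ctr)^2)))
    expect_equal(sort(unique(round(d / nsize, 9))), c(1, round(sqrt(2), 9)))
    expect_equal(sum(abs(d - nsize) <= 1e-9 * nsize), 4L)
  }
})

test_that("cell_containing inverts cell_centre for both shapes", {
  set.seed(7)
  for (shape in c("square", "hex")) {
    spec <- neighbourhood_spec(shape, runif(1, 1, 300))
    for (rep in 1:25) {
      cell <- sample(-30:30, 2)
      expect_identical(cell_containing(cell_centre(cell, spec), spec), cell)
    }
  }
})

test_that("a 200 m neighbourhood cell over a 100 m raster aggregates exactly 4 values, mean by Eq. of the mean", {
  vals <- matrix(c(2, 6, 4, 8), 2, 2)  # column-major: members {2,6,4,8}
  s <- cost_surface(vals, resolution = 100)
  spec <- neighbourhood_spec("square", 200)
  mem <- cell_members(s, c(0L, 0L), spec)
  expect_equal(nrow(mem), 4L)
  expect_equal(aggregate_cell_cost(s, c(0L, 0L), spec), 5)
})

test_that("aggregation over a constant surface returns that constant for any footprint", {
  s <- cost_surface(matrix(7.25, 30, 30), resolution = 10)
  for (shape in c("square", "hex")) {
    for (nsize in c(10, 25, 37.5)) {
      spec <- neighbourhood_spec(shape, nsize)
      cell <- cell_containing(c(150, -150) + s$origin, spec, s$origin)
      expect_equal(aggregate_cell_cost(s, cell, spec), 7.25)
    }
  }
})

test_that("nsize equal to the resolution with an anchored lattice recovers single raster values", {
  s <- random_surface(10, 10, res = 5, seed = 3)
  spec <- neighbourhood_spec("square", 5)
  for (i in 1:10) for (j in 1:10) {
    expect_equal(aggregate_cell_cost(s, c(i - 1L, j - 1L), spec),
                 s$values[i, j])
  }
})

test_that("aggregated means match the arithmetic oracle on random fixtures, both shapes", {
  for (seed in 1:5) {
    s <- random_surface(18, 22, res = 1, seed = seed)
    for (shape in c("square", "hex")) {
      spec <- neighbourhood_spec(shape, 2.7)
      cell <- cell_containing(c(s$origin[1] + 9.3, s$origin[2] - 8.1), spec, s$origin)
      got <- aggregate_cell_cost(s, cell, spec)
      want <- oracle_cell_cost(s, cell, shape, 2.7)
      expect_equal(got, want, tolerance = 1e-12)
      # bounded by member range
      mem <- cell_members(s, cell, spec)
      expect_gte(got, min(s$values[mem]))
      expect_lte(got, max(s$values[mem]))
    }
  }
})

test_that("NoData handling: excluded from means, all-NoData cells invalid, out-of-extent invalid", {
  vals <- matrix(c(2, 6, NA, 8), 2, 2)
  s <- cost_surface(vals, resolution = 100)
  spec <- neighbourhood_spec("square", 200)
  expect_equal(aggregate_cell_cost(s, c(0L, 0L), spec), mean(c(2, 6, 8)))

  s2 <- cost_surface(matrix(NA_real_, 2, 2), resolution = 100)
  expect_true(is.na(aggregate_cell_cost(s2, c(0L, 0L), spec)))
  # footprint entirely outside the raster
  expect_true(is.na(aggregate_cell_cost(s, c(50L, 50L), spec)))
})

test_that("nsize below the raster resolution falls back to the value under the footprint centre", {
  s <- cost_surface(matrix(as.numeric(1:16), 4, 4), resolution = 100)
  spec <- neighbourhood_spec("square", 20)  # 5x5 lattice cells per raster cell
  cell <- cell_containing(c(165, -255) + s$origin, spec, s$origin)
  expect_equal(nrow(cell_members(s, cell, spec)), 0L)
  expect_equal(aggregate_cell_cost(s, cell, spec),
               s$values[3, 2])  # raster cell under the footprint centre
})

test_that("neighbourhood costs match direct raster lookup for an anchored unit lattice", {
  s <- cost_surface(matrix(as.numeric(1:25), 5, 5), resolution = 1)
  spec <- neighbourhood_spec("square", 1)
  nb <- neighbourhood_costs(s, c(2L, 2L), spec)  # lattice (2,2) = raster [3,3]
  expect_equal(nrow(nb), 8L)
  for (k in seq_len(nrow(nb)))
    expect_equal(nb$cost[k], s$values[nb$c1[k] + 1L, nb$c2[k] + 1L])
})

test_that("hex interiors see 6 neighbours and raster-boundary cells see fewer", {
  s <- cost_surface(matrix(5, 30, 30), resolution = 1)
  hx <- neighbourhood_spec("hex", 1)
  interior <- cell_containing(c(15, -15) + s$origin, hx, s$origin)
  expect_equal(nrow(neighbourhood_costs(s, interior, hx)), 6L)

  sq <- neighbourhood_spec("square", 1)
  corner <- c(0L, 0L)
  expect_lt(nrow(neighbourhood_costs(s, corner, sq)), 8L)
})
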