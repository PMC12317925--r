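# Independent brute-force reference implementations used as oracles.
# These deliberately share no geometry code with the package: square
# membership is a direct bounds test, hex membership a half-plane test
# against the six world-space neighbour directions, and the greedy walk
# re-derives everything per step by scanning the whole raster.

SQ3 <- sqrt(3)

oracle_hex_centre <- function(q, r, s, anchor = c(0, 0)) {
  c(anchor[1] + s * (q + r / 2), anchor[2] - s * (SQ3 / 2) * r)
}

# point in the pointy-top hexagon centred at `ctr` with centre spacing s:
# closer to ctr than to each of the six adjacent centres (half-planes).
oracle_in_hex <- function(px, py, ctr, s) {
  dirs <- rbind(c(s, 0), c(s / 2, SQ3 / 2 * s), c(-s / 2, SQ3 / 2 * s),
                c(-s, 0), c(-s / 2, -SQ3 / 2 * s), c(s / 2, -SQ3 / 2 * s))
  dx <- px - ctr[1]; dy <- py - ctr[2]
  ok <- rep(TRUE, length(px))
  for (k in 1:6) ok <- ok & (dx * dirs[k, 1] + dy * dirs[k, 2] < s^2 / 2)
  ok
}

# hex cell containing a world point: nearest centre among a scanned window
oracle_hex_containing <- function(p, s, anchor = c(0, 0)) {
  r0 <- round((anchor[2] - p[2]) / (s * SQ3 / 2))
  q0 <- round((p[1] - anchor[1]) / s - r0 / 2)
  best <- NULL; bestd <- Inf
  for (q in (q0 - 2):(q0 + 2)) for (r in (r0 - 2):(r0 + 2)) {
    d <- sum((p - oracle_hex_centre(q, r, s, anchor))^2)
    if (d < bestd) { bestd <- d; best <- c(q, r) }
  }
  best
}

# mean cost of one lattice cell by scanning every raster cell centre
oracle_cell_cost <- function(surface, cell, shape, s, anchor = surface$origin) {
  res <- surface$resolution
  nr <- nrow(surface$values); nc <- ncol(surface$values)
  g <- expand.grid(i = seq_len(nr), j = seq_len(nc))
  px <- surface$origin[1] + (g$j - 0.5) * res
  py <- surface$origin[2] - (g$i - 0.5) * res
  inside <- if (shape == "square") {
    x0 <- anchor[1] + cell[2] * s; y1 <- anchor[2] - cell[1] * s
    px >= x0 & px < x0 + s & py <= y1 & py > y1 - s
  } else {
    oracle_in_hex(px, py, oracle_hex_centre(cell[1], cell[2], s, anchor), s)
  }
  vals <- surface$values[cbind(g$i, g$j)][inside]
  vals <- vals[!is.na(vals)]
  if (length(vals)) return(mean(vals))
  # footprint holds no raster centre: sample the value under its centre
  ctr <- if (shape == "square") {
    c(anchor[1] + (cell[2] + 0.5) * s, anchor[2] - (cell[1] + 0.5) * s)
  } else oracle_hex_centre(cell[1], cell[2], s, anchor)
  ii <- floor((surface$origin[2] - ctr[2]) / res) + 1
  jj <- floor((ctr[1] - surface$origin[1]) / res) + 1
  if (ii < 1 || jj < 1 || ii > nr || jj > nc) NA_real_
  else surface$values[ii, jj]
}

oracle_cell_inside <- function(surface, cell, shape, s, anchor = surface$origin) {
  ext <- c(surface$origin[1],
           surface$origin[1] + ncol(surface$values) * surface$resolution,
           surface$origin[2] - nrow(surface$values) * surface$resolution,
           surface$origin[2])
  eps <- 1e-9 * surface$resolution
  if (shape == "square") {
    x0 <- anchor[1] + cell[2] * s; y1 <- anchor[2] - cell[1] * s
    bb <- c(x0, x0 + s, y1 - s, y1)
  } else {
    ctr <- oracle_hex_centre(cell[1], cell[2], s, anchor)
    bb <- c(ctr[1] - s / 2, ctr[1] + s / 2, ctr[2] - s / SQ3, ctr[2] + s / SQ3)
  }
  bb[1] >= ext[1] - eps && bb[2] <= ext[2] + eps &&
    bb[3] >= ext[3] - eps && bb[4] <= ext[4] + eps
}

ORACLE_SQUARE_OFFSETS <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                               c(0, 1), c(1, -1), c(1, 0), c(1, 1))
ORACLE_HEX_OFFSETS <- rbind(c(1, 0), c(1, -1), c(0, -1), c(-1, 0),
                            c(-1, 1), c(0, 1))

# greedy reference walk; stops comparison when a tie (relative 1e-9) or
# an all-visited fallback would require a random draw.
oracle_greedy_walk <- function(surface, shape, s, start, n_steps) {
  cur <- if (shape == "square") {
    c(floor((surface$origin[2] - start[2]) / s),
      floor((start[1] - surface$origin[1]) / s))
  } else oracle_hex_containing(start, s, surface$origin)
  offs <- if (shape == "square") ORACLE_SQUARE_OFFSETS else ORACLE_HEX_OFFSETS
  cells <- matrix(cur, 1, 2)
  visited <- walk_cell_key(cur)
  status <- "completed_steps"; ambiguous <- FALSE
  if (n_steps > 0) for (t in seq_len(n_steps)) {
    cand <- list(); costs <- numeric(0)
    for (k in seq_len(nrow(offs))) {
      cell <- cur + offs[k, ]
      if (!oracle_cell_inside(surface, cell, shape, s)) next
      cost <- oracle_cell_cost(surface, cell, shape, s)
      if (is.na(cost)) next
      cand[[length(cand) + 1L]] <- cell
      costs <- c(costs, cost)
    }
    if (!length(cand)) { status <- "hit_edge"; break }
    unvis <- which(!vapply(cand, walk_cell_key, "") %in% visited)
    if (!length(unvis)) { ambiguous <- TRUE; break }
    m <- min(costs[unvis])
    tied <- unvis[costs[unvis] <= m + 1e-9 * abs(m)]
    if (length(tied) > 1L) { ambiguous <- TRUE; break }
    cur <- cand[[tied]]
    cells <- rbind(cells, cur)
    visited <- c(visited, walk_cell_key(cur))
  }
  cells <- unname(cells)
  storage.mode(cells) <- "integer"
  list(cells = cells, status = status, ambiguous = ambiguous)
}

# random continuous test surface (ties have probability zero)
random_surface <- function(nr = 20, nc = 20, res = 1, seed = 1) {
  set.seed(seed)
  cost_surface(matrix(runif(nr * nc, 1, 10), nr, nc), resolution = res)
}

# hand-built walk object for statistics tests
make_walk <- function(cells, spec, anchor = c(0, 0), status = "completed_steps",
                      fallback = NULL) {
  cells <- matrix(as.integer(cells), ncol = 2)
  centres <- cell_centre(cells, spec, anchor)
  if (!is.matrix(centres)) centres <- matrix(centres, ncol = 2)
  steps <- if (nrow(cells) > 1)
    sqrt(diff(centres[, 1])^2 + diff(centres[, 2])^2) else numeric(0)
  structure(list(cells = cells, centres = centres, step_lengths = steps,
                 fallback = if (is.null(fallback)) rep(FALSE, length(steps))
                            else fallback,
                 status = status, spec = spec, anchor = anchor,
                 seed = NA_integer_),
            class = "walk")
}

# access to the internal per-walk coverage routine
walk_covered_cells_for_test <- function(walk, surface)
  costwalk:::walk_covered_cells(walk, surface)
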