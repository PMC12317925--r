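#' Batch configuration
#'
#' One model configuration: neighbourhood shape and size, number of
#' repeated walks, timesteps per walk, start policy and master seed. The
#' defaults (100 runs of 1000 timesteps, random starts) are the standard
#' exploratory design for this model family.
#'
#' @param spec A [neighbourhood_spec].
#' @param n_runs Number of walks (>= 0).
#' @param n_steps Timesteps per walk (>= 0).
#' @param start `"random"` or a fixed world `(x, y)` coordinate.
#' @param master_seed Integer master seed; each walk runs on an
#'   independent, reproducible substream derived from
#'   `(master_seed, walk index)`.
#' @return An object of class `batch_config`.
#' @export
batch_config <- function(spec, n_runs = 100L, n_steps = 1000L,
                         start = "random", master_seed = 1L) {
  stopifnot(inherits(spec, "nbhd_spec"))
  if (n_runs < 0 || n_runs != floor(n_runs)) stop("`n_runs` must be a non-negative integer")
  if (n_steps < 0 || n_steps != floor(n_steps)) stop("`n_steps` must be a non-negative integer")
  if (!identical(start, "random") && (!is.numeric(start) || length(start) != 2L))
    stop("`start` must be \"random\" or a world (x, y) coordinate")
  structure(list(spec = spec, n_runs = as.integer(n_runs),
                 n_steps = as.integer(n_steps), start = start,
                 master_seed = as.integer(master_seed)),
            class = "batch_config")
}

# Per-walk substream seed: a fixed affine map of (master seed, walk index)
# into the 32-bit seed space. Keeps batches bit-reproducible and walks
# independent of execution order.
walk_seed <- function(master_seed, walk_index) {
  as.integer((as.double(master_seed) %% 2147483647 + 11 * walk_index) %% 2147483647)
}

#' Run a batch of seeded walks
#'
#' Executes `n_runs` walks under one configuration, each on its own
#' reproducible RNG substream, and accumulates the aggregate walk-density
#' raster and the per-walk statistics table. Rerunning with the same
#' configuration and master seed reproduces the result bit-identically.
#'
#' @param surface A [cost_surface].
#' @param config A [batch_config].
#' @return An object of class `batch_result`: list with `walks` (list of
#'   [run_walk()] results), `density` (integer matrix aligned to
#'   `surface`, counting distinct walks per raster cell), `stats` (data
#'   frame, one row per walk — see [walk_stats_table()]) and `config`.
#' @export
run_batch <- function(surface, config) {
  stopifnot(inherits(surface, "cost_surface"), inherits(config, "batch_config"))
  walks <- vector("list", config$n_runs)
  for (w in seq_len(config$n_runs)) {
    walks[[w]] <- run_walk(surface, config$spec, config$start, config$n_steps,
                           seed = walk_seed(config$master_seed, w))
  }
  structure(
    list(walks = walks,
         density = density_raster(walks, surface),
         stats = walk_stats_table(walks),
         config = config),
    class = "batch_result"
  )
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf("<batch_result> %d walks (%s ring, nsize %g, %d steps, seed %d)\n",
              length(x$walks), x$config$spec$shape, x$config$spec$nsize,
              x$config$n_steps, x$config$master_seed))
  cat(sprintf("  hit edge: %d of %d; max walk density: %d\n",
              sum(vapply(x$walks, function(w) w$status == "hit_edge", logical(1))),
              length(x$walks), if (length(x$walks)) max(x$density) else 0L))
  invisible(x)
}

#' Walk-density raster
#'
#' For each walk the polyline of consecutive cell centres is rasterised
#' onto the cost surface's own grid with a supercover line traversal
#' (every raster cell the segment passes through is marked, including all
#' four cells around an exactly-crossed corner), and each raster cell is
#' incremented at most once per walk. The result counts, per raster cell,
#' the number of *distinct* walks that crossed it.
#'
#' @param walks List of [run_walk()] results sharing one surface frame.
#' @param surface The [cost_surface] defining the output grid.
#' @return Integer matrix with the surface's dimensions.
#' @export
density_raster <- function(walks, surface) {
  stopifnot(inherits(surface, "cost_surface"))
  nr <- nrow(surface$values); nc <- ncol(surface$values)
  dens <- matrix(0L, nr, nc)
  for (w in walks) {
    cells <- walk_covered_cells(w, surface)
    if (nrow(cells)) dens[cells] <- dens[cells] + 1L
  }
  dens
}

# Unique raster (row, col) cells covered by one walk's centre polyline.
walk_covered_cells <- function(walk, surface) {
  ctr <- walk$centres
  n <- nrow(ctr)
  if (n == 1L) {
    idx <- raster_index_at(surface, ctr[1, 1], ctr[1, 2])
    segs <- if (is.null(idx)) matrix(integer(), 0L, 2L) else matrix(idx, 1L, 2L)
  } else {
    segs <- do.call(rbind, lapply(seq_len(n - 1L), function(k) {
      supercover_cells(ctr[k, 1], ctr[k, 2], ctr[k + 1L, 1], ctr[k + 1L, 2], surface)
    }))
  }
  unique(segs)
}

# Supercover traversal of one world-coordinate segment on the raster grid.
# Works in continuous grid coordinates (u = column position, v = row
# position); cells between consecutive gridline crossings are identified
# by their midpoints, and a crossing through a grid corner adds all four
# adjacent cells. Returns in-grid (row, col) indices.
supercover_cells <- function(x0, y0, x1, y1, surface) {
  res <- surface$resolution
  u0 <- (x0 - surface$origin[1]) / res; u1 <- (x1 - surface$origin[1]) / res
  v0 <- (surface$origin[2] - y0) / res; v1 <- (surface$origin[2] - y1) / res
  du <- u1 - u0; dv <- v1 - v0

  tu <- if (abs(du) > 0) {
    ks <- seq(ceiling(min(u0, u1)), floor(max(u0, u1)))
    (ks - u0) / du
  } else numeric(0)
  tv <- if (abs(dv) > 0) {
    ks <- seq(ceiling(min(v0, v1)), floor(max(v0, v1)))
    (ks - v0) / dv
  } else numeric(0)
  tu <- tu[tu > 0 & tu < 1]; tv <- tv[tv > 0 & tv < 1]
  ts <- sort(unique(c(0, tu, tv, 1)))

  mids <- (ts[-length(ts)] + ts[-1L]) / 2
  cells <- cbind(floor(v0 + mids * dv) + 1, floor(u0 + mids * du) + 1)

  # corner crossings: a t present in both crossing sets touches 4 cells
  if (length(tu) && length(tv)) {
    corner <- tu[vapply(tu, function(t) any(abs(tv - t) < 1e-12), logical(1))]
    for (t in corner) {
      cu <- round(u0 + t * du); cv <- round(v0 + t * dv)
      cells <- rbind(cells,
                     cbind(c(cv, cv, cv + 1, cv + 1), c(cu, cu + 1, cu, cu + 1)))
    }
  }
  nr <- nrow(surface$values); nc <- ncol(surface$values)
  keep <- cells[, 1] >= 1 & cells[, 1] <= nr & cells[, 2] >= 1 & cells[, 2] <= nc
  cells <- cells[keep, , drop = FALSE]
  storage.mode(cells) <- "integer"
  unique(cells)
}
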