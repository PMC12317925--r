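#' Choose the agent's next cell
#'
#' The cellular-automata transition rule: the agent moves to the
#' neighbourhood cell with the minimum aggregated cost among cells it has
#' not already visited. If two or more unvisited candidates tie for the
#' minimum (within relative tolerance 1e-9, so that ties on flat or
#' integer-valued terrain are recognised despite floating-point
#' arithmetic), one is chosen uniformly at random. If every candidate has
#' been visited — the see-saw guard has excluded them all — one candidate
#' is drawn uniformly at random from the whole ring (the fallback), and
#' the event is flagged. An empty candidate set signals edge termination.
#'
#' @param costs A data frame as returned by [neighbourhood_costs()].
#' @param visited Character vector of visited-cell keys (see
#'   [walk_cell_key()]).
#' @return `NULL` when `costs` is empty (terminate); otherwise a list with
#'   `index` (the chosen row of `costs`) and `fallback` (`TRUE` when the
#'   all-visited fallback fired). Draws from the current RNG stream.
#' @export
select_next <- function(costs, visited = character()) {
  if (nrow(costs) == 0L) return(NULL)
  keys <- paste(costs$c1, costs$c2, sep = ",")
  unvis <- which(!(keys %in% visited))
  if (length(unvis)) {
    m <- min(costs$cost[unvis])
    tied <- unvis[costs$cost[unvis] <= m + 1e-9 * abs(m)]
    idx <- if (length(tied) == 1L) tied else tied[sample.int(length(tied), 1L)]
    list(index = idx, fallback = FALSE)
  } else {
    list(index = sample.int(nrow(costs), 1L), fallback = TRUE)
  }
}

#' Key identifying a lattice cell in the visited set
#'
#' Previously visited locations are tracked at the granularity of lattice
#' cells occupied by the agent (not raster cells merely crossed).
#'
#' @param cell Integer lattice coordinate pair.
#' @return A single string.
#' @export
walk_cell_key <- function(cell) paste(cell[1], cell[2], sep = ",")

# Neighbourhood costs with a per-walk memo of aggregated cell costs.
# Neighbourhoods along a walk overlap heavily, so caching the (expensive)
# raster aggregation per lattice cell speeds long walks up considerably.
neighbourhood_costs_cached <- function(surface, centre, spec, anchor, cache) {
  off <- neighbour_offsets(spec$shape)
  rows <- vector("list", nrow(off))
  for (k in seq_len(nrow(off))) {
    cell <- c(centre[1] + off[k, 1], centre[2] + off[k, 2])
    key <- walk_cell_key(cell)
    hit <- cache[[key]]
    if (is.null(hit)) {
      hit <- if (!cell_inside_extent(cell, spec, surface, anchor)) NA_real_
             else aggregate_cell_cost(surface, cell, spec, anchor)
      cache[[key]] <- hit
    }
    if (is.na(hit)) next
    rows[[k]] <- c(off[k, 1], off[k, 2], cell[1], cell[2], hit)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- as.data.frame(do.call(rbind, c(rows, list(matrix(numeric(), 0L, 5L)))))
  names(out) <- c("d1", "d2", "c1", "c2", "cost")
  out
}

#' Run one least-cost walk
#'
#' Starting from `start` (a world coordinate, or `"random"` for a
#' uniformly chosen valid lattice cell), the agent repeatedly evaluates
#' the aggregated costs of its single-ring neighbourhood and relocates by
#' [select_next()]. The walk ends after `n_steps` moves (status
#' `"completed_steps"`) or as soon as no valid candidate remains — every
#' neighbour's footprint leaves the raster or is entirely NoData (status
#' `"hit_edge"`). Neighbours only partly outside the raster are excluded
#' rather than terminal, so walks may hug the map edge.
#'
#' @param surface A [cost_surface].
#' @param spec A [neighbourhood_spec].
#' @param start World `(x, y)` inside the raster on a valid cell, or
#'   `"random"`.
#' @param n_steps Maximum number of moves (>= 0).
#' @param seed Optional integer seed; when given, the walk is a pure
#'   function of its arguments and the caller's RNG state is untouched.
#' @return An object of class `walk`: list with `cells` (n x 2 integer
#'   lattice coordinates), `centres` (n x 2 world coordinates),
#'   `step_lengths`, `fallback` (logical per step), `status`, `spec`,
#'   `anchor`, `seed`.
#' @examples
#' s <- generate_surface("tilted_plane", 20, 20, resolution = 1, gradient = c(1, 0))
#' w <- run_walk(s, neighbourhood_spec("square", 1), start = c(10.5, 10.5),
#'               n_steps = 5, seed = 1)
#' @export
run_walk <- function(surface, spec, start, n_steps, seed = NULL) {
  stopifnot(inherits(surface, "cost_surface"), inherits(spec, "nbhd_spec"))
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 0 ||
      n_steps != floor(n_steps))
    stop("`n_steps` must be a non-negative integer")
  anchor <- surface$origin

  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
  }

  if (identical(start, "random")) {
    cur <- random_start_cell(surface, spec, anchor)
  } else {
    if (!is.numeric(start) || length(start) != 2L)
      stop("`start` must be a world (x, y) coordinate or \"random\"")
    idx <- raster_index_at(surface, start[1], start[2])
    if (is.null(idx)) stop("start coordinate lies outside the raster extent")
    if (is.na(surface$values[idx[1], idx[2]]))
      stop("start coordinate lies on a NoData cell")
    cur <- cell_containing(start, spec, anchor)
  }

  cache <- new.env(parent = emptyenv())
  visited <- new.env(parent = emptyenv())
  assign(walk_cell_key(cur), TRUE, envir = visited)

  n_alloc <- n_steps + 1L
  cells <- matrix(NA_integer_, n_alloc, 2L)
  cells[1L, ] <- cur
  fallback <- logical(0)
  status <- "completed_steps"
  n_cells <- 1L

  if (n_steps > 0) for (t in seq_len(n_steps)) {
    costs <- neighbourhood_costs_cached(surface, cur, spec, anchor, cache)
    vis_keys <- if (nrow(costs)) {
      keys <- paste(costs$c1, costs$c2, sep = ",")
      keys[vapply(keys, function(k) !is.null(visited[[k]]), logical(1))]
    } else character()
    sel <- select_next(costs, vis_keys)
    if (is.null(sel)) { status <- "hit_edge"; break }
    cur <- c(as.integer(costs$c1[sel$index]), as.integer(costs$c2[sel$index]))
    n_cells <- n_cells + 1L
    cells[n_cells, ] <- cur
    fallback <- c(fallback, sel$fallback)
    assign(walk_cell_key(cur), TRUE, envir = visited)
  }

  cells <- cells[seq_len(n_cells), , drop = FALSE]
  centres <- cell_centre(cells, spec, anchor)
  step_lengths <- if (n_cells > 1L)
    sqrt(diff(centres[, 1])^2 + diff(centres[, 2])^2) else numeric(0)

  structure(
    list(cells = cells, centres = centres, step_lengths = step_lengths,
         fallback = fallback, status = status, spec = spec, anchor = anchor,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "walk"
  )
}

#' @export
print.walk <- function(x, ...) {
  cat(sprintf("<walk> %d cells (%d steps), %s ring nsize %g, status: %s\n",
              nrow(x$cells), length(x$step_lengths), x$spec$shape, x$spec$nsize,
              x$status))
  cat(sprintf("  total distance %g, fallback events: %d\n",
              sum(x$step_lengths), sum(x$fallback)))
  invisible(x)
}

# Uniformly sample a valid, fully-in-extent lattice cell by rejection:
# a uniform point in the extent lands in each fully-interior cell with
# equal probability, so accepted draws are uniform over valid cells.
random_start_cell <- function(surface, spec, anchor, max_tries = 10000L) {
  ext <- surface_extent(surface)
  for (k in seq_len(max_tries)) {
    p <- c(stats::runif(1, ext[1], ext[2]), stats::runif(1, ext[3], ext[4]))
    cell <- cell_containing(p, spec, anchor)
    if (!cell_inside_extent(cell, spec, surface, anchor)) next
    if (is.na(aggregate_cell_cost(surface, cell, spec, anchor))) next
    return(cell)
  }
  stop("no valid start cell found (surface may be all NoData)")
}
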