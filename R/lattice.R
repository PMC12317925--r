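#' Neighbourhood specification
#'
#' The agent's decision catchment: a single ring of cells around its
#' current lattice cell, either the 8-cell square Moore ring or the
#' 6-cell hexagonal ring, with cells of edge-to-edge size `nsize` map
#' units. For hexagons, `nsize` is the centre-to-centre distance between
#' adjacent cells, so every hex step has length exactly `nsize`; for
#' squares, orthogonal steps are `nsize` and diagonal steps
#' `nsize * sqrt(2)`.
#'
#' @param shape `"square"` or `"hex"`.
#' @param nsize Neighbourhood cell size in map units (> 0).
#' @return An object of class `nbhd_spec`.
#' @examples
#' neighbourhood_spec("hex", 500)
#' @export
neighbourhood_spec <- function(shape = c("square", "hex"), nsize) {
  shape <- match.arg(shape)
  if (!is.numeric(nsize) || length(nsize) != 1L || !is.finite(nsize) || nsize <= 0)
    stop("`nsize` must be a single positive number (map units)")
  structure(list(shape = shape, nsize = as.numeric(nsize)), class = "nbhd_spec")
}

#' @export
print.nbhd_spec <- function(x, ...) {
  cat(sprintf("<nbhd_spec> %s ring (%d cells), nsize = %g map units\n", x$shape,
              if (x$shape == "square") 8L else 6L, x$nsize))
  invisible(x)
}

#' Single-ring neighbour offsets
#'
#' The fixed, documented enumeration order of the ring — required so that
#' seeded tie-breaking is reproducible across platforms. Square (Moore)
#' offsets are `(di, dj)` row/column displacements enumerated row-major
#' from the north-west corner; hexagonal offsets are axial `(dq, dr)`
#' displacements enumerated counter-clockwise from due east.
#'
#' @param shape `"square"` or `"hex"`.
#' @return An integer matrix with one offset per row; columns `di, dj`
#'   (square) or `dq, dr` (hex).
#' @export
neighbour_offsets <- function(shape) {
  if (length(shape) != 1L || !shape %in% c("square", "hex"))
    stop("unknown neighbourhood shape: ", paste(shape, collapse = ", "))
  if (shape == "square") {
    m <- cbind(di = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
               dj = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  } else {
    m <- cbind(dq = c(1L, 1L, 0L, -1L, -1L, 0L),
               dr = c(0L, -1L, -1L, 0L, 1L, 1L))
  }
  m
}

#' World coordinate of a lattice cell centre
#'
#' Square lattice cells are indexed `(i, j)` (row, column, 0-based) with
#' centre `anchor + ((j + 0.5) * nsize, -(i + 0.5) * nsize)` — north-up,
#' matching the raster convention. Hex cells use pointy-top axial
#' coordinates `(q, r)` with centre
#' `anchor + (nsize * (q + r/2), -nsize * sqrt(3)/2 * r)`, which places
#' all six neighbours exactly `nsize` away.
#'
#' @param cell Integer pair: `(i, j)` for square, `(q, r)` for hex. May
#'   also be a matrix with one cell per row.
#' @param spec A [neighbourhood_spec].
#' @param anchor World coordinate of the lattice anchor (cell `(0, 0)`'s
#'   north-west corner for squares; cell `(0, 0)`'s centre offset for hex).
#' @return Numeric `(x, y)` (or an n x 2 matrix).
#' @export
cell_centre <- function(cell, spec, anchor = c(0, 0)) {
  stopifnot(inherits(spec, "nbhd_spec"))
  m <- if (is.matrix(cell)) cell else matrix(cell, ncol = 2L)
  s <- spec$nsize
  out <- if (spec$shape == "square") {
    cbind(anchor[1] + (m[, 2] + 0.5) * s, anchor[2] - (m[, 1] + 0.5) * s)
  } else {
    cbind(anchor[1] + s * (m[, 1] + m[, 2] / 2),
          anchor[2] - s * (sqrt(3) / 2) * m[, 2])
  }
  if (is.matrix(cell)) out else drop(out)
}

#' Lattice cell containing a world point
#'
#' Inverse of [cell_centre()]. Square cells are half-open (west/north
#' edges inclusive). Hex membership is nearest-centre (the Voronoi cell of
#' a hex lattice is the hexagon itself), computed by fractional axial
#' coordinates with cube rounding; points equidistant from two centres
#' are resolved deterministically by the rounding rule.
#'
#' @inheritParams cell_centre
#' @param point World `(x, y)`.
#' @return Integer pair of lattice coordinates.
#' @export
cell_containing <- function(point, spec, anchor = c(0, 0)) {
  stopifnot(inherits(spec, "nbhd_spec"))
  s <- spec$nsize
  if (spec$shape == "square") {
    c(as.integer(floor((anchor[2] - point[2]) / s)),
      as.integer(floor((point[1] - anchor[1]) / s)))
  } else {
    rf <- (anchor[2] - point[2]) / (s * sqrt(3) / 2)
    qf <- (point[1] - anchor[1]) / s - rf / 2
    axial_round(qf, rf)
  }
}

# Cube-rounding of fractional axial coordinates to the containing hex.
axial_round <- function(qf, rf) {
  xf <- qf; zf <- rf; yf <- -xf - zf
  x <- round(xf); y <- round(yf); z <- round(zf)
  dx <- abs(x - xf); dy <- abs(y - yf); dz <- abs(z - zf)
  if (dx > dy && dx > dz) x <- -y - z
  else if (dy > dz) y <- -x - z
  else z <- -x - y
  c(as.integer(x), as.integer(z))
}

# World-coordinate bounding box [xmin, xmax, ymin, ymax] of a cell footprint.
# The hexagon attains its bbox extremes (side midpoints in x, vertices in y),
# so axis-aligned containment checks via the bbox are exact.
cell_bbox <- function(cell, spec, anchor = c(0, 0)) {
  s <- spec$nsize
  if (spec$shape == "square") {
    x0 <- anchor[1] + cell[2] * s
    y1 <- anchor[2] - cell[1] * s
    c(x0, x0 + s, y1 - s, y1)
  } else {
    ctr <- cell_centre(cell, spec, anchor)
    r <- s / sqrt(3)  # circumradius of a pointy-top hex with centre spacing s
    c(ctr[1] - s / 2, ctr[1] + s / 2, ctr[2] - r, ctr[2] + r)
  }
}

# Is the cell footprint entirely inside the surface extent?
# Tolerance lets footprints sharing an edge with the extent count as inside.
cell_inside_extent <- function(cell, spec, surface, anchor = surface$origin) {
  bb <- cell_bbox(cell, spec, anchor)
  ext <- surface_extent(surface)
  eps <- 1e-9 * surface$resolution
  bb[1] >= ext[1] - eps && bb[2] <= ext[2] + eps &&
    bb[3] >= ext[3] - eps && bb[4] <= ext[4] + eps
}

#' Raster cells belonging to a neighbourhood cell
#'
#' Membership follows the centre rule: a raster value belongs to the
#' neighbourhood cell whose footprint contains the raster-cell centre.
#' Square footprints are half-open (west/north edges inclusive); hex
#' membership is nearest-centre. This generalises cleanly to hexagons and
#' to `nsize` that is not an integer multiple of the raster resolution.
#'
#' @param surface A [cost_surface].
#' @param cell Integer lattice coordinates of the neighbourhood cell.
#' @param spec A [neighbourhood_spec].
#' @param anchor Lattice anchor; defaults to the raster origin.
#' @return Integer matrix of raster `(row, col)` indices (possibly 0 rows).
#' @export
cell_members <- function(surface, cell, spec, anchor = surface$origin) {
  stopifnot(inherits(surface, "cost_surface"), inherits(spec, "nbhd_spec"))
  res <- surface$resolution
  nr <- nrow(surface$values); nc <- ncol(surface$values)
  bb <- cell_bbox(cell, spec, anchor)

  # candidate raster index window covering the footprint bbox
  jlo <- max(1L, floor((bb[1] - surface$origin[1]) / res - 0.5) + 1L)
  jhi <- min(nc, ceiling((bb[2] - surface$origin[1]) / res + 0.5))
  ilo <- max(1L, floor((surface$origin[2] - bb[4]) / res - 0.5) + 1L)
  ihi <- min(nr, ceiling((surface$origin[2] - bb[3]) / res + 0.5))
  if (jlo > jhi || ilo > ihi) return(matrix(integer(), 0L, 2L))

  jj <- jlo:jhi; ii <- ilo:ihi
  xc <- surface$origin[1] + (jj - 0.5) * res
  yc <- surface$origin[2] - (ii - 0.5) * res

  if (spec$shape == "square") {
    inx <- xc >= bb[1] & xc < bb[2]
    iny <- yc <= bb[4] & yc > bb[3]   # top edge inclusive, bottom exclusive
    ii <- ii[iny]; jj <- jj[inx]
    if (!length(ii) || !length(jj)) return(matrix(integer(), 0L, 2L))
    cbind(rep(ii, times = length(jj)), rep(jj, each = length(ii)))
  } else {
    g <- expand.grid(i = ii, j = jj, KEEP.OUT.ATTRS = FALSE)
    px <- surface$origin[1] + (g$j - 0.5) * res
    py <- surface$origin[2] - (g$i - 0.5) * res
    s <- spec$nsize
    rf <- ((anchor[2] - py)) / (s * sqrt(3) / 2)
    qf <- (px - anchor[1]) / s - rf / 2
    keep <- vapply(seq_len(nrow(g)), function(k) {
      all(axial_round(qf[k], rf[k]) == cell)
    }, logical(1))
    cbind(g$i[keep], g$j[keep])
  }
}

#' Aggregate raster cost into a neighbourhood cell
#'
#' The cost of a neighbourhood cell is the arithmetic mean of the raster
#' values whose cell centres fall inside its footprint, NoData excluded.
#' When the footprint contains no raster-cell centre (`nsize` smaller
#' than the raster resolution), the raster value at the footprint centre
#' is used instead. Returns `NA` (the invalid marker) when no valid value
#' is available — all members NoData, or footprint outside the raster.
#'
#' @inheritParams cell_members
#' @return A single cost value, or `NA_real_`.
#' @examples
#' # a 200 m cell over a 100 m raster takes the mean of exactly 4 values
#' s <- cost_surface(matrix(c(2, 6, 4, 8), 2, 2), resolution = 100)
#' aggregate_cell_cost(s, c(0L, 0L), neighbourhood_spec("square", 200))  # 5
#' @export
aggregate_cell_cost <- function(surface, cell, spec, anchor = surface$origin) {
  mem <- cell_members(surface, cell, spec, anchor)
  if (nrow(mem) == 0L) {
    ctr <- cell_centre(cell, spec, anchor)
    idx <- raster_index_at(surface, ctr[1], ctr[2])
    if (is.null(idx)) return(NA_real_)
    return(surface$values[idx[1], idx[2]])  # NA when NoData
  }
  vals <- surface$values[mem]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Aggregated costs of a full neighbourhood ring
#'
#' Evaluates [aggregate_cell_cost()] for every cell in the single ring
#' around `centre`. Neighbours whose footprint extends beyond the raster
#' extent, and neighbours with no valid cost (all NoData), are omitted;
#' an empty result is legal and is interpreted by the walker as edge
#' termination.
#'
#' @inheritParams cell_members
#' @param centre Lattice coordinates of the agent's current cell.
#' @return A data frame with one row per valid neighbour: offset columns
#'   (`d1`, `d2`), absolute cell coordinates (`c1`, `c2`) and `cost`,
#'   in the fixed [neighbour_offsets()] order.
#' @export
neighbourhood_costs <- function(surface, centre, spec, anchor = surface$origin) {
  off <- neighbour_offsets(spec$shape)
  rows <- vector("list", nrow(off))
  for (k in seq_len(nrow(off))) {
    cell <- c(centre[1] + off[k, 1], centre[2] + off[k, 2])
    if (!cell_inside_extent(cell, spec, surface, anchor)) next
    cost <- aggregate_cell_cost(surface, cell, spec, anchor)
    if (is.na(cost)) next
    rows[[k]] <- c(off[k, 1], off[k, 2], cell[1], cell[2], cost)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- as.data.frame(do.call(rbind, c(rows, list(matrix(numeric(), 0L, 5L)))))
  names(out) <- c("d1", "d2", "c1", "c2", "cost")
  out
}
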