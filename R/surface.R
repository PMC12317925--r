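#' Construct a cost surface
#'
#' A cost surface is a single-band, north-up, square-pixel georeferenced
#' grid of friction values (e.g. terrain slope in degrees) over which
#' agents walk. Row 1 is the northernmost row; the pixel at row `i`,
#' column `j` (1-based) has its centre at
#' `origin + ((j - 0.5) * resolution, -(i - 0.5) * resolution)`.
#'
#' @param values Numeric matrix of cost values. `NA` entries are treated
#'   as NoData.
#' @param resolution Cell edge length in map units (> 0).
#' @param origin Numeric length-2 vector, world coordinate `(x, y)` of the
#'   grid's top-left corner.
#' @param crs Opaque coordinate-reference identifier (free-form string,
#'   e.g. WKT or an EPSG code); `NA` when unknown.
#' @return An object of class `cost_surface`: a list with elements
#'   `values` (matrix, NoData as `NA`), `resolution`, `origin`, `crs`.
#' @examples
#' s <- cost_surface(matrix(1:12, 3, 4), resolution = 100, origin = c(0, 300))
#' @export
cost_surface <- function(values, resolution, origin = c(0, nrow(values) * resolution),
                         crs = NA_character_) {
  if (!is.matrix(values) || nrow(values) < 1L || ncol(values) < 1L)
    stop("`values` must be a matrix with at least one row and one column")
  if (!is.numeric(resolution) || length(resolution) != 1L || !is.finite(resolution) ||
      resolution <= 0)
    stop("`resolution` must be a single positive number")
  if (length(origin) != 2L || !all(is.finite(origin)))
    stop("`origin` must be a finite (x, y) coordinate")
  storage.mode(values) <- "double"
  if (any(is.infinite(values), na.rm = TRUE))
    stop("non-NoData cost values must be finite")
  structure(
    list(values = values, resolution = as.numeric(resolution),
         origin = as.numeric(origin), crs = crs),
    class = "cost_surface"
  )
}

#' @export
print.cost_surface <- function(x, ...) {
  v <- x$values
  cat(sprintf("<cost_surface> %d x %d cells @ %g map units\n", nrow(v), ncol(v),
              x$resolution))
  cat(sprintf("  origin (top-left): (%g, %g)   CRS: %s\n", x$origin[1], x$origin[2],
              if (is.na(x$crs)) "<unset>" else x$crs))
  cat(sprintf("  cost range: [%g, %g]   NoData cells: %d\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

# World-coordinate extent [xmin, xmax, ymin, ymax] of a surface.
surface_extent <- function(surface) {
  res <- surface$resolution
  c(surface$origin[1], surface$origin[1] + ncol(surface$values) * res,
    surface$origin[2] - nrow(surface$values) * res, surface$origin[2])
}

# Raster (row, col) index containing a world point, or NULL when outside.
# Half-open pixels: left/top edge inclusive.
raster_index_at <- function(surface, x, y) {
  res <- surface$resolution
  j <- floor((x - surface$origin[1]) / res) + 1
  i <- floor((surface$origin[2] - y) / res) + 1
  if (i < 1 || j < 1 || i > nrow(surface$values) || j > ncol(surface$values))
    return(NULL)
  c(i, j)
}

#' Read a cost surface from an Esri ASCII grid
#'
#' Reads the plain-text Esri ASCII raster format (`ncols`/`nrows`/
#' `xllcorner`/`yllcorner`/`cellsize`/`nodata_value` header followed by
#' rows of values, north first). If a sidecar `.prj` file with the same
#' stem exists, its contents are stored as the CRS identifier.
#'
#' @param path Path to a readable `.asc` file.
#' @return A [cost_surface].
#' @seealso [write_cost_surface()]
#' @export
read_cost_surface <- function(path) {
  if (!file.exists(path)) stop("cannot read raster: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L) stop("malformed ASCII grid (fewer than 6 lines): ", path)

  header <- list()
  n_head <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                   "yllcenter", "cellsize", "nodata_value")) {
      val <- suppressWarnings(as.numeric(parts[2]))
      if (length(parts) != 2L || is.na(val))
        stop("malformed ASCII grid header line: ", ln)
      header[[key]] <- val
      n_head <- n_head + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(header)))
    stop("ASCII grid header missing required keys: ",
         paste(setdiff(need, names(header)), collapse = ", "))
  if (header$cellsize <= 0) stop("ASCII grid cellsize must be positive")
  nc <- as.integer(header$ncols); nr <- as.integer(header$nrows)

  body <- scan(text = paste(lines[-seq_len(n_head)], collapse = "\n"),
               what = numeric(), quiet = TRUE)
  if (length(body) != nr * nc)
    stop(sprintf("ASCII grid body has %d values, expected %d x %d = %d",
                 length(body), nr, nc, nr * nc))
  vals <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(header$nodata_value))
    vals[vals == header$nodata_value] <- NA_real_

  # Lower-left corner or lower-left cell centre both define the origin.
  xll <- if (!is.null(header$xllcorner)) header$xllcorner
         else if (!is.null(header$xllcenter)) header$xllcenter - header$cellsize / 2
         else 0
  yll <- if (!is.null(header$yllcorner)) header$yllcorner
         else if (!is.null(header$yllcenter)) header$yllcenter - header$cellsize / 2
         else 0
  prj <- sub("\\.asc$", ".prj", path, ignore.case = TRUE)
  crs <- if (prj != path && file.exists(prj))
    paste(readLines(prj, warn = FALSE), collapse = "\n") else NA_character_

  cost_surface(vals, resolution = header$cellsize,
               origin = c(xll, yll + nr * header$cellsize), crs = crs)
}

#' Write a cost surface to an Esri ASCII grid
#'
#' Values are written at full double precision so a write/read round trip
#' reproduces the surface exactly. NoData cells are written as -9999 (or a
#' smaller value if -9999 occurs in the data). When the surface carries a
#' CRS string, a sidecar `.prj` file is written next to the grid.
#'
#' @param surface A [cost_surface].
#' @param path Output path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_cost_surface <- function(surface, path) {
  stopifnot(inherits(surface, "cost_surface"))
  v <- surface$values
  nodata <- -9999
  while (any(v == nodata, na.rm = TRUE)) nodata <- nodata * 10
  res <- surface$resolution
  header <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.17g", surface$origin[1]),
    sprintf("yllcorner %.17g", surface$origin[2] - nrow(v) * res),
    sprintf("cellsize %.17g", res),
    sprintf("nodata_value %.17g", nodata)
  )
  out <- v
  out[is.na(out)] <- nodata
  rows <- apply(out, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(header, rows), path)
  if (!is.na(surface$crs))
    writeLines(surface$crs, sub("\\.asc$", ".prj", path, ignore.case = TRUE))
  invisible(path)
}

#' Slope (degrees) from a digital elevation model
#'
#' Horn's 3x3 finite-difference estimator: for each interior cell the
#' east-west gradient p and north-south gradient q are weighted sums of
#' the 8 neighbours (weights 1-2-1, divided by 8 * resolution) and slope
#' is `atan(sqrt(p^2 + q^2))` converted to degrees. Border cells, and any
#' cell whose 3x3 window touches NoData, are NoData in the output.
#'
#' @param dem A [cost_surface] whose values are elevations in the same
#'   linear units as the resolution.
#' @return A [cost_surface] of slope in degrees, in `[0, 90)`.
#' @export
slope_from_dem <- function(dem) {
  stopifnot(inherits(dem, "cost_surface"))
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3L || nc < 3L) stop("DEM must be at least 3 x 3 cells")
  res <- dem$resolution

  # 3x3 window shifts; rows run north -> south so i+1 is the southern row.
  sh <- function(di, dj) z[(2 + di):(nr - 1 + di), (2 + dj):(nc - 1 + dj)]
  nw <- sh(-1, -1); n_ <- sh(-1, 0); ne <- sh(-1, 1)
  w_ <- sh(0, -1);                   e_ <- sh(0, 1)
  sw <- sh(1, -1);  s_ <- sh(1, 0);  se <- sh(1, 1)

  p <- ((ne + 2 * e_ + se) - (nw + 2 * w_ + sw)) / (8 * res)
  q <- ((sw + 2 * s_ + se) - (nw + 2 * n_ + ne)) / (8 * res)
  interior <- atan(sqrt(p^2 + q^2)) * 180 / pi
  # Horn's stencil omits the centre cell, but a NoData centre still voids
  # the whole 3x3 window
  interior[is.na(sh(0, 0))] <- NA_real_
  slope <- matrix(NA_real_, nr, nc)
  slope[2:(nr - 1), 2:(nc - 1)] <- interior
  cost_surface(slope, dem$resolution, dem$origin, dem$crs)
}

#' Generate a synthetic cost surface
#'
#' Deterministic (per seed) fixture surfaces with the structure the walker
#' is designed for: smooth low-cost corridors embedded in higher-cost
#' terrain, optionally ringed by a NoData margin.
#'
#' Kinds:
#' \describe{
#'   \item{`tilted_plane`}{`cost = base + gradient[1] * x + gradient[2] * y`
#'     evaluated at cell centres (world coordinates relative to the
#'     origin). A gradient of `c(1, 0)` makes every row an arithmetic
#'     progression increasing eastward.}
#'   \item{`parabolic_valley`}{a north-south trough:
#'     `cost = base + curvature * (x - axis_x)^2`, i.e. each row's minimum
#'     lies on the valley axis — a synthetic analogue of a low-cost river
#'     corridor flanked by ridges.}
#'   \item{`random_field`}{smooth correlated noise: seeded white noise
#'     blurred with a separable Gaussian kernel of standard deviation
#'     `correlation` cells, rescaled to standard deviation `sd` around
#'     `base` and clamped at zero (costs are non-negative).}
#' }
#'
#' @param kind One of `"tilted_plane"`, `"parabolic_valley"`,
#'   `"random_field"`.
#' @param nrow,ncol Grid dimensions (>= 3).
#' @param resolution Cell size in map units.
#' @param base Baseline cost level.
#' @param gradient Length-2 cost gradient per map unit (tilted_plane).
#' @param axis_x World x of the valley axis; defaults to mid-grid
#'   (parabolic_valley).
#' @param curvature Quadratic wall steepness per map unit squared
#'   (parabolic_valley).
#' @param correlation Blur standard deviation in cells (random_field).
#' @param sd Marginal standard deviation of the field (random_field).
#' @param nodata_margin Width, in cells, of a NoData ring around the grid.
#' @param seed Integer RNG seed (random_field only).
#' @param origin World coordinate of the top-left corner.
#' @return A [cost_surface].
#' @examples
#' s <- generate_surface("parabolic_valley", 40, 60, resolution = 100)
#' @export
generate_surface <- function(kind = c("tilted_plane", "parabolic_valley", "random_field"),
                             nrow, ncol, resolution = 1,
                             base = 10, gradient = c(1, 0),
                             axis_x = NULL, curvature = NULL,
                             correlation = 3, sd = 3,
                             nodata_margin = 0L, seed = 1L,
                             origin = c(0, nrow * resolution)) {
  kind <- match.arg(kind)
  if (nrow < 3L || ncol < 3L) stop("surface must be at least 3 x 3 cells")
  if (resolution <= 0) stop("`resolution` must be positive")
  if (nodata_margin < 0 || 2 * nodata_margin >= min(nrow, ncol) - 2)
    stop("`nodata_margin` leaves no interior cells")

  xc <- origin[1] + (seq_len(ncol) - 0.5) * resolution
  yc <- origin[2] - (seq_len(nrow) - 0.5) * resolution

  vals <- switch(kind,
    tilted_plane = {
      if (length(gradient) != 2L) stop("`gradient` must have length 2")
      outer(yc, xc, function(y, x) base + gradient[1] * x + gradient[2] * y)
    },
    parabolic_valley = {
      if (is.null(axis_x)) axis_x <- origin[1] + ncol * resolution / 2
      if (is.null(curvature)) curvature <- 1 / (ncol * resolution)
      if (curvature <= 0) stop("`curvature` must be positive")
      outer(yc, xc, function(y, x) base + curvature * (x - axis_x)^2)
    },
    random_field = {
      if (correlation <= 0 || sd < 0) stop("invalid random_field parameters")
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(as.integer(seed))
      noise <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
      sm <- gaussian_blur(noise, correlation)
      sm <- (sm - mean(sm)) / stats::sd(sm)
      pmax(base + sd * sm, 0)
    })

  if (nodata_margin > 0L) {
    m <- seq_len(nodata_margin)
    vals[m, ] <- NA_real_; vals[nrow - m + 1L, ] <- NA_real_
    vals[, m] <- NA_real_; vals[, ncol - m + 1L] <- NA_real_
  }
  cost_surface(vals, resolution, origin)
}

# Separable Gaussian blur with reflected edges; sigma in cells. The
# kernel is truncated at 3 sigma (and at the grid size for tiny grids)
# and renormalised.
gaussian_blur <- function(m, sigma) {
  blur1 <- function(mat) {
    nr <- nrow(mat)
    half <- min(max(1L, ceiling(3 * sigma)), nr - 1L)
    k <- stats::dnorm(-half:half, sd = sigma)
    k <- k / sum(k)
    idx <- c(rev(seq_len(half)), seq_len(nr), nr - seq_len(half) + 1L)
    padded <- mat[idx, , drop = FALSE]
    out <- matrix(0, nr, ncol(mat))
    for (o in seq_along(k))
      out <- out + k[o] * padded[(o - 1L) + seq_len(nr), , drop = FALSE]
    out
  }
  t(blur1(t(blur1(m))))
}

# Save/restore .Random.seed so generators don't disturb the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
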