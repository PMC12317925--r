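#' Export walks as GeoJSON point and line files
#'
#' Writes two GeoJSON FeatureCollections next to each other: a points
#' file (one feature per visited cell centre, attributed with run id and
#' step index) and a lines file (one LineString per walk, attributed with
#' run id, termination status, total and resultant distance, deviation
#' percentage and azimuth). Coordinates are the exact lattice cell
#' centres in the source raster's map units; when the surface carried a
#' CRS string it is recorded in each file's `crs_id` foreign member.
#'
#' @param walks Non-empty list of [run_walk()] results sharing one frame.
#' @param path_points,path_lines Output file paths.
#' @param crs Optional CRS identifier string to record.
#' @return Invisibly, `c(path_points, path_lines)`.
#' @export
export_walks <- function(walks, path_points, path_lines, crs = NA_character_) {
  if (!length(walks)) stop("`walks` must be a non-empty list of walks")
  stopifnot(all(vapply(walks, inherits, logical(1), "walk")))

  pt_feats <- list()
  for (k in seq_along(walks)) {
    ctr <- walks[[k]]$centres
    for (s in seq_len(nrow(ctr))) {
      pt_feats[[length(pt_feats) + 1L]] <- list(
        type = "Feature",
        geometry = list(type = "Point", coordinates = c(ctr[s, 1], ctr[s, 2])),
        properties = list(run = k, step = s - 1L)
      )
    }
  }
  ln_feats <- lapply(seq_along(walks), function(k) {
    w <- walks[[k]]
    d <- walk_distances(w)
    coords <- lapply(seq_len(nrow(w$centres)),
                     function(s) c(w$centres[s, 1], w$centres[s, 2]))
    list(type = "Feature",
         geometry = list(type = "LineString", coordinates = coords),
         properties = list(run = k, status = w$status,
                           total_distance = d$total_distance,
                           resultant_distance = d$resultant_distance,
                           deviation_pct = d$deviation_pct,
                           azimuth_deg = d$azimuth_deg))
  })

  fc <- function(features) {
    obj <- list(type = "FeatureCollection", features = features)
    if (!is.na(crs)) obj$crs_id <- crs
    obj
  }
  jsonlite::write_json(fc(pt_feats), path_points, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  jsonlite::write_json(fc(ln_feats), path_lines, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(c(path_points, path_lines))
}

#' Write a walk-density grid as an Esri ASCII raster
#'
#' The density grid is written on the cost surface's own grid (same
#' dimensions, resolution and origin), so it overlays the input raster
#' cell-for-cell in any GIS.
#'
#' @param density Integer matrix from [density_raster()].
#' @param surface The [cost_surface] that defines the grid frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_density <- function(density, surface, path) {
  stopifnot(inherits(surface, "cost_surface"),
            all(dim(density) == dim(surface$values)))
  write_cost_surface(
    cost_surface(density + 0, surface$resolution, surface$origin, surface$crs),
    path
  )
}

#' Write a machine-readable run manifest
#'
#' Records everything needed to reproduce a batch: the full
#' configuration, master seed, input raster path, package version and
#' per-walk termination/fallback summary.
#'
#' @param result A [run_batch()] result.
#' @param path Output JSON path.
#' @param cost_raster Path of the input raster (recorded verbatim).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(result, path, cost_raster = NA_character_) {
  stopifnot(inherits(result, "batch_result"))
  cfg <- result$config
  manifest <- list(
    tool = "costwalk",
    version = as.character(utils::packageVersion("costwalk")),
    cost_raster = cost_raster,
    shape = cfg$spec$shape,
    nsize = cfg$spec$nsize,
    n_runs = cfg$n_runs,
    n_steps = cfg$n_steps,
    start = if (identical(cfg$start, "random")) "random" else cfg$start,
    master_seed = cfg$master_seed,
    walks = list(
      hit_edge = sum(vapply(result$walks, function(w) w$status == "hit_edge",
                            logical(1))),
      completed = sum(vapply(result$walks, function(w) w$status == "completed_steps",
                             logical(1))),
      fallback_events = sum(vapply(result$walks, function(w) sum(w$fallback),
                                   integer(1)))
    )
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
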