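# Readers and writers. Coordinates in all files are expected to be planar
# meters already (projection from geographic coordinates happens upstream,
# per dataset); the package never re-projects.

.geojson_geom_to_region <- function(geom) {
  ring_mat <- function(ring) {
    do.call(rbind, lapply(ring, function(pt) c(pt[[1L]], pt[[2L]])))
  }
  if (geom$type == "Polygon") {
    planar_region(list(lapply(geom$coordinates, ring_mat)))
  } else if (geom$type == "MultiPolygon") {
    planar_region(lapply(geom$coordinates, function(poly) lapply(poly, ring_mat)))
  } else {
    stop(sprintf("unsupported geometry type '%s'", geom$type))
  }
}

.region_to_geojson_geom <- function(region) {
  part_coords <- lapply(region$parts, function(part) {
    lapply(part, function(r) {
      rc <- rbind(r, r[1L, , drop = FALSE])  # close the ring
      lapply(seq_len(nrow(rc)), function(k) c(rc[k, 1L], rc[k, 2L]))
    })
  })
  if (length(part_coords) == 1L) {
    list(type = "Polygon", coordinates = part_coords[[1L]])
  } else {
    list(type = "MultiPolygon", coordinates = part_coords)
  }
}

.feature_id <- function(props, keys) {
  for (k in keys) if (!is.null(props[[k]])) return(as.character(props[[k]]))
  NULL
}

#' Read census tracts from GeoJSON
#'
#' Each feature needs a `tract_id` (or `id`) property; group counts are taken
#' from feature properties named after [group_order()], or joined from a CSV
#' attribute table with columns `tract_id` plus the group names.
#'
#' @param path GeoJSON file (planar coordinates, meters).
#' @param demographics_csv optional CSV to join counts from.
#' @return list of [tract()] objects.
#' @export
read_tracts_geojson <- function(path, demographics_csv = NULL) {
  gj <- jsonlite::read_json(path)
  demo <- NULL
  if (!is.null(demographics_csv)) {
    demo <- utils::read.csv(demographics_csv, stringsAsFactors = FALSE,
                            colClasses = c(tract_id = "character"))
  }
  lapply(gj$features, function(f) {
    id <- .feature_id(f$properties, c("tract_id", "id"))
    if (is.null(id)) stop("tract feature without tract_id property")
    counts <- NULL
    if (!is.null(demo)) {
      row <- demo[demo$tract_id == id, , drop = FALSE]
      if (nrow(row) != 1L) stop(sprintf("tract '%s' missing from demographics table", id))
      counts <- unlist(row[1L, intersect(group_order(), names(row)), drop = FALSE])
    } else {
      have <- intersect(group_order(), names(f$properties))
      if (length(have) > 0L) counts <- unlist(f$properties[have])
    }
    tract(id, .geojson_geom_to_region(f$geometry), counts)
  })
}

#' Read park polygons from GeoJSON
#'
#' @param path GeoJSON file with `park_id` (or `id`) feature properties.
#' @return list of [park()] objects.
#' @export
read_parks_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  lapply(gj$features, function(f) {
    id <- .feature_id(f$properties, c("park_id", "id"))
    if (is.null(id)) stop("park feature without park_id property")
    tags <- f$properties$source_tags
    park(id, .geojson_geom_to_region(f$geometry),
         source_tags = if (is.null(tags)) character(0) else unlist(tags))
  })
}

#' Read raw OSM-style tagged polygon candidates from GeoJSON
#'
#' Features carry a `tags` property map; use [filter_osm_parks()] on the
#' result to keep the park-like records.
#'
#' @param path GeoJSON file.
#' @return list of records with `id`, `tags` and `region`.
#' @export
read_osm_records_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  lapply(seq_along(gj$features), function(k) {
    f <- gj$features[[k]]
    id <- .feature_id(f$properties, c("id", "osm_id"))
    if (is.null(id)) id <- as.character(k)
    region <- if (is.null(f$geometry)) NULL else .geojson_geom_to_region(f$geometry)
    list(id = id, tags = f$properties$tags, region = region)
  })
}

#' Write parks to GeoJSON
#'
#' Merged parks serialize their member polygons as a MultiPolygon and record
#' the input ids they absorbed in an `absorbed_ids` property.
#'
#' @param parks list of [park()] objects.
#' @param path output file.
#' @export
write_parks_geojson <- function(parks, path) {
  features <- lapply(parks, function(p) {
    list(type = "Feature",
         properties = list(park_id = p$park_id,
                           area_km2 = p$area_km2,
                           absorbed_ids = paste(p$absorbed_ids, collapse = ";"),
                           source_tags = paste(p$source_tags, collapse = ";")),
         geometry = .region_to_geojson_geom(p$region))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trajectory table from CSV
#'
#' Expected columns: `agent_id`, `kind` (home/other), `x`, `y`, optional
#' `slot`; one home row per agent.
#'
#' @param path CSV file.
#' @return a [trajectory_set()].
#' @export
read_trajectories_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(agent_id = "character"))
  trajectory_set(df)
}

#' Write a trajectory table to CSV
#' @param trajectories a [trajectory_set()].
#' @param path output file.
#' @export
write_trajectories_csv <- function(trajectories, path) {
  utils::write.csv(as.data.frame(trajectories), path, row.names = FALSE)
  invisible(path)
}

#' Write an exposure network as MatrixMarket plus id maps
#'
#' Writes `<path>` (MTX, deterministic row-major order), `<path>.rows.csv`
#' (row index to tract_id) and `<path>.cols.csv` (column index to park_id).
#'
#' @param net an [exposure_network()].
#' @param path output `.mtx` path.
#' @export
write_network_mtx <- function(net, path) {
  X <- methods::as(net$X, "TsparseMatrix")
  o <- order(X@i, X@j)
  Xs <- Matrix::sparseMatrix(i = X@i[o] + 1L, j = X@j[o] + 1L, x = X@x[o],
                             dims = dim(X))
  Matrix::writeMM(Xs, path)
  utils::write.csv(data.frame(row = seq_along(net$tract_ids),
                              tract_id = net$tract_ids),
                   paste0(path, ".rows.csv"), row.names = FALSE)
  utils::write.csv(data.frame(col = seq_along(net$park_ids),
                              park_id = net$park_ids),
                   paste0(path, ".cols.csv"), row.names = FALSE)
  invisible(path)
}

#' Read an exposure network from MatrixMarket plus id maps
#'
#' @param path `.mtx` path written by [write_network_mtx()].
#' @param radius_m exposure radius to record.
#' @return an [exposure_network()].
#' @export
read_network_mtx <- function(path, radius_m = 200) {
  X <- Matrix::readMM(path)
  rows <- utils::read.csv(paste0(path, ".rows.csv"), stringsAsFactors = FALSE)
  cols <- utils::read.csv(paste0(path, ".cols.csv"), stringsAsFactors = FALSE)
  exposure_network(X, rows$tract_id, cols$park_id, radius_m = radius_m)
}

#' Write tracts to GeoJSON (with group counts as properties)
#' @param tracts list of [tract()] objects.
#' @param path output file.
#' @export
write_tracts_geojson <- function(tracts, path) {
  features <- lapply(tracts, function(t) {
    props <- c(list(tract_id = t$tract_id, area_km2 = t$area_km2),
               as.list(t$group_counts))
    list(type = "Feature", properties = props,
         geometry = .region_to_geojson_geom(t$region))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
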