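# Core spatial data model: tracts, parks, tag filtering, overlap merging,
# home-tract assignment and per-tract park-area fraction.

#' Canonical racial/ethnic group order
#'
#' The fixed order used everywhere for deterministic tie-breaking: ties in
#' predominant-group labeling resolve to the earliest group in this order.
#'
#' @return character vector `c("White", "Black", "Asian", "Hispanic", "Other")`.
#' @export
group_order <- function() c("White", "Black", "Asian", "Hispanic", "Other")

#' Census tract
#'
#' @param tract_id character id.
#' @param region a [planar_region()] with positive area.
#' @param group_counts named non-negative counts over [group_order()]
#'   (missing groups default to 0).
#' @return object of class `tract`.
#' @export
tract <- function(tract_id, region, group_counts = NULL) {
  stopifnot(is.character(tract_id), length(tract_id) == 1L,
            inherits(region, "planar_region"))
  counts <- stats::setNames(rep(0, 5L), group_order())
  if (!is.null(group_counts)) {
    if (is.null(names(group_counts)) ||
        !all(names(group_counts) %in% group_order())) {
      stop("group_counts must be named with groups from group_order()")
    }
    if (any(group_counts < 0)) stop("group_counts must be non-negative")
    counts[names(group_counts)] <- as.numeric(group_counts)
  }
  a <- region_area(region)
  if (a <= 0) stop(sprintf("tract '%s' has non-positive area", tract_id))
  structure(list(tract_id = tract_id, region = region,
                 group_counts = counts, area_km2 = a / 1e6),
            class = "tract")
}

#' Park
#'
#' @param park_id character id.
#' @param region a [planar_region()].
#' @param area_km2 optional; if supplied it must agree with the region area to
#'   1e-9 relative tolerance, otherwise it is computed.
#' @param source_tags character vector of originating tag strings.
#' @param absorbed_ids ids of the original polygons this park absorbed through
#'   merging (itself, initially).
#' @return object of class `park`.
#' @export
park <- function(park_id, region, area_km2 = NULL, source_tags = character(),
                 absorbed_ids = park_id) {
  stopifnot(is.character(park_id), length(park_id) == 1L,
            inherits(region, "planar_region"))
  a <- region_area(region) / 1e6
  if (!is.null(area_km2)) {
    if (a > 0 && abs(area_km2 - a) > 1e-9 * a) {
      stop(sprintf("park '%s': supplied area_km2 (%.9g) does not match region area (%.9g)",
                   park_id, area_km2, a))
    }
  }
  structure(list(park_id = park_id, region = region, area_km2 = a,
                 source_tags = source_tags,
                 absorbed_ids = sort(absorbed_ids)),
            class = "park")
}

#' @export
print.tract <- function(x, ...) {
  cat(sprintf("<tract %s: %.4g km^2, pop %d>\n", x$tract_id, x$area_km2,
              round(sum(x$group_counts))))
  invisible(x)
}

#' @export
print.park <- function(x, ...) {
  cat(sprintf("<park %s: %.4g km^2, absorbed %d polygon(s)>\n",
              x$park_id, x$area_km2, length(x$absorbed_ids)))
  invisible(x)
}

tract_ids <- function(tracts) vapply(tracts, function(t) t$tract_id, "")
park_ids <- function(parks) vapply(parks, function(p) p$park_id, "")
park_areas_km2 <- function(parks) vapply(parks, function(p) p$area_km2, 0)

# Tag/value pairs that make an OSM polygon a park.
.PARK_TAGS <- list(
  leisure = c("park", "dog_park", "playground", "garden", "golf_course"),
  landuse = c("recreation_ground", "nature_reserve"),
  natural = "beach",
  boundary = "protected_area"
)

#' Filter OSM-tagged polygon records down to parks
#'
#' Keeps records whose tag map matches any of: leisure = park, dog_park,
#' playground, garden or golf_course; landuse = recreation_ground or
#' nature_reserve; natural = beach; boundary = protected_area.
#'
#' @param records list of records, each a list with fields `id`, `tags`
#'   (named character vector/list) and `region` (a [planar_region()], possibly
#'   NULL/missing).
#' @return list of [park()] objects (tag matches with geometry); records
#'   without geometry are dropped with a warning, their count in attribute
#'   `n_no_geometry`.
#' @export
filter_osm_parks <- function(records) {
  matches <- function(tags) {
    if (is.null(tags) || length(tags) == 0L) return(FALSE)
    tags <- unlist(tags)
    for (key in names(.PARK_TAGS)) {
      if (!is.na(tags[key]) && tags[key] %in% .PARK_TAGS[[key]]) return(TRUE)
    }
    FALSE
  }
  keep <- vapply(records, function(r) matches(r$tags), TRUE)
  kept <- records[keep]
  has_geom <- vapply(kept, function(r) inherits(r$region, "planar_region"), TRUE)
  n_bad <- sum(!has_geom)
  if (n_bad > 0L) {
    warning(sprintf("%d matching record(s) lack geometry and were rejected", n_bad))
  }
  out <- lapply(kept[has_geom], function(r) {
    tags <- unlist(r$tags)
    park(as.character(r$id), r$region,
         source_tags = paste(names(tags), tags, sep = "="))
  })
  attr(out, "n_no_geometry") <- n_bad
  out
}

# Positive-area overlap threshold: relative to the smaller polygon, with an
# absolute floor of 1e-6 m^2 so boundary-touching polygons (measure ~ 0) never
# merge.
.overlap_eps <- function(a1, a2) max(1e-9 * min(a1, a2), 1e-6)

#' Merge overlapping parks into a spatially disjoint set
#'
#' Finds connected components of the positive-area pairwise-overlap graph and
#' merges each component into one park whose region is the union of its
#' members (kept as parts; the area is the measure of the union). Equivalent
#' to iterated pairwise merging, but order-independent. Idempotent.
#'
#' @param parks list of [park()] objects.
#' @return list of disjoint [park()] objects; each records the input ids it
#'   absorbed in `$absorbed_ids`. Ordered by park_id.
#' @export
merge_overlapping_parks <- function(parks) {
  n <- length(parks)
  if (n <= 1L) return(parks[order(park_ids(parks))])
  bb <- lapply(parks, function(p) .region_bbox(p$region))
  areas <- vapply(parks, function(p) p$area_km2 * 1e6, 0)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (!.bbox_overlap(bb[[i]], bb[[j]])) next
      if (find(i) == find(j)) next
      inter <- region_intersection_area(parks[[i]]$region, parks[[j]]$region)
      if (inter > .overlap_eps(areas[i], areas[j])) {
        parent[find(j)] <- find(i)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  out <- lapply(split(seq_len(n), roots), function(idx) {
    members <- parks[idx]
    ids <- sort(unlist(lapply(members, function(p) p$absorbed_ids)))
    region <- planar_region(do.call(c, lapply(members, function(p) p$region$parts)))
    park(min(park_ids(members)), region,
         source_tags = sort(unique(unlist(lapply(members, function(p) p$source_tags)))),
         absorbed_ids = ids)
  })
  out <- unname(out)
  out[order(park_ids(out))]
}

#' Assign points to the census tract containing them
#'
#' Points on a shared boundary are assigned to the tract with the
#' lexicographically smallest id (deterministic tie-break).
#'
#' @param points two-column matrix of x, y in meters (or length-2 vector).
#' @param tracts list of [tract()] objects with interior-disjoint regions.
#' @return character vector of tract ids, `NA` for points outside all tracts.
#'   Attribute `n_boundary` counts points resolved by the boundary tie-break.
#' @export
assign_home_tract <- function(points, tracts) {
  pts <- .as_points(points)
  ord <- order(tract_ids(tracts))
  assigned <- rep(NA_character_, nrow(pts))
  bb <- lapply(tracts, function(t) .region_bbox(t$region))
  for (i in ord) {
    open <- which(is.na(assigned))
    if (length(open) == 0L) break
    b <- bb[[i]]
    inbb <- pts[open, 1L] >= b["xmin"] & pts[open, 1L] <= b["xmax"] &
      pts[open, 2L] >= b["ymin"] & pts[open, 2L] <= b["ymax"]
    cand <- open[inbb]
    if (length(cand) == 0L) next
    hit <- region_contains(pts[cand, , drop = FALSE], tracts[[i]]$region)
    assigned[cand[hit]] <- tracts[[i]]$tract_id
  }
  # boundary rescue: ray casting can leave an exactly-on-boundary point
  # unclaimed; give it to the smallest-id tract whose boundary it touches
  n_boundary <- 0L
  open <- which(is.na(assigned))
  if (length(open) > 0L) {
    for (i in ord) {
      if (length(open) == 0L) break
      d <- region_distance(pts[open, , drop = FALSE], tracts[[i]]$region)
      onb <- d <= 1e-9
      if (any(onb)) {
        assigned[open[onb]] <- tracts[[i]]$tract_id
        n_boundary <- n_boundary + sum(onb)
        open <- open[!onb]
      }
    }
  }
  attr(assigned, "n_boundary") <- n_boundary
  assigned
}

#' Fraction of each tract's area covered by parks
#'
#' For each tract, area(tract intersected with the union of all parks) divided
#' by the tract area. Parks are expected to be merged (disjoint), but the
#' computation is exact for overlapping parks too (union measure).
#'
#' @param tracts list of [tract()] objects.
#' @param parks list of [park()] objects.
#' @return named numeric vector in `[0, 1]`, one entry per tract_id.
#' @export
park_area_fraction <- function(tracts, parks) {
  out <- stats::setNames(numeric(length(tracts)), tract_ids(tracts))
  if (length(tracts) == 0L) return(out)
  pbb <- lapply(parks, function(p) .region_bbox(p$region))
  for (k in seq_along(tracts)) {
    tr <- tracts[[k]]
    ta <- region_area(tr$region)
    if (ta <= 0) stop(sprintf("tract '%s' has zero area", tr$tract_id))
    tb <- .region_bbox(tr$region)
    near <- which(vapply(pbb, .bbox_overlap, TRUE, tb))
    if (length(near) == 0L) { out[k] <- 0; next }
    ed_t <- .region_edges(tr$region, set = 1L)
    eds_p <- vector("list", length(near))
    off <- 0L
    for (q in seq_along(near)) {
      eds_p[[q]] <- .region_edges(parks[[near[q]]]$region, set = 2L, poly_offset = off)
      off <- off + length(parks[[near[q]]]$region$parts)
    }
    inter <- .slab_sweep(c(list(ed_t), eds_p), op = "intersect")["area"]
    out[k] <- min(1, max(0, unname(inter) / ta))
  }
  out
}
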