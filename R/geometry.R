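# Planar geometry engine.
#
# All coordinates are planar meters (projection happens upstream, at I/O time).
# A region is a list of "parts"; each part is a list of rings (matrices with
# columns x, y; first ring is the outer boundary, further rings are holes,
# interpreted even-odd). Parts of one region MAY overlap each other: a merged
# park keeps its original member polygons as parts and its area is the measure
# of their union. Areas of unions/intersections are computed exactly (up to
# float) by a slab (trapezoid) decomposition: the x-axis is cut at every vertex
# and every pairwise edge crossing, so inside each open slab the covered
# y-measure is linear in x and can be integrated from midpoint (or Gauss-point)
# evaluations.

.normalize_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (ncol(ring) < 2L) stop("ring must have two coordinate columns")
  ring <- ring[, 1:2, drop = FALSE]
  storage.mode(ring) <- "double"
  if (!all(is.finite(ring))) stop("ring coordinates must be finite")
  n <- nrow(ring)
  if (n >= 2L && all(ring[1L, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  if (nrow(ring) < 3L) stop("ring must have at least 3 distinct vertices")
  dimnames(ring) <- NULL
  ring
}

#' Construct a planar region
#'
#' A region is one or more polygon parts, each a list of rings (outer ring
#' first, optional holes after; even-odd rule). Coordinates are planar meters.
#'
#' @param parts a single ring matrix, a list of ring matrices (one single-ring
#'   part each), or a list of parts where each part is a list of ring matrices.
#' @return an object of class `planar_region`.
#' @export
planar_region <- function(parts) {
  if (is.matrix(parts) || is.data.frame(parts)) parts <- list(list(parts))
  if (!is.list(parts)) stop("parts must be a matrix or a list")
  parts <- lapply(parts, function(p) {
    if (is.matrix(p) || is.data.frame(p)) p <- list(p)
    lapply(p, .normalize_ring)
  })
  structure(list(parts = parts), class = "planar_region")
}

#' @export
print.planar_region <- function(x, ...) {
  nr <- sum(vapply(x$parts, length, 1L))
  cat(sprintf("<planar_region: %d part(s), %d ring(s), area %.6g km^2>\n",
              length(x$parts), nr, region_area(x) / 1e6))
  invisible(x)
}

.ring_area_signed <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  sum(x * ys - xs * y) / 2
}

.region_edges <- function(region, set = 1L, poly_offset = 0L) {
  out <- vector("list", length(region$parts))
  for (k in seq_along(region$parts)) {
    rings <- region$parts[[k]]
    segs <- lapply(rings, function(r) {
      n <- nrow(r)
      cbind(x1 = r[, 1L], y1 = r[, 2L],
            x2 = r[c(2:n, 1L), 1L], y2 = r[c(2:n, 1L), 2L])
    })
    m <- do.call(rbind, segs)
    out[[k]] <- cbind(m, poly = poly_offset + k, set = set)
  }
  do.call(rbind, out)
}

.region_bbox <- function(region) {
  xs <- unlist(lapply(region$parts, function(p) lapply(p, function(r) r[, 1L])))
  ys <- unlist(lapply(region$parts, function(p) lapply(p, function(r) r[, 2L])))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

.bbox_overlap <- function(a, b, pad = 0) {
  a["xmin"] - pad <= b["xmax"] && b["xmin"] - pad <= a["xmax"] &&
    a["ymin"] - pad <= b["ymax"] && b["ymin"] - pad <= a["ymax"]
}

# x-coordinates where edge pairs properly cross; needed as slab boundaries so
# the interval structure is constant inside a slab. Same-polygon pairs are
# included so even self-intersecting rings are measured correctly (even-odd);
# edges that merely share an endpoint are excluded by the strict (0,1) test.
.crossing_xs <- function(ed) {
  n <- nrow(ed)
  if (n < 2L) return(numeric(0))
  exmin <- pmin(ed[, "x1"], ed[, "x2"]); exmax <- pmax(ed[, "x1"], ed[, "x2"])
  eymin <- pmin(ed[, "y1"], ed[, "y2"]); eymax <- pmax(ed[, "y1"], ed[, "y2"])
  ovx <- outer(exmin, exmax, "<=") & t(outer(exmin, exmax, "<="))
  ovy <- outer(eymin, eymax, "<=") & t(outer(eymin, eymax, "<="))
  cand <- which(ovx & ovy & upper.tri(ovx), arr.ind = TRUE)
  if (nrow(cand) == 0L) return(numeric(0))
  i <- cand[, 1L]; j <- cand[, 2L]
  rx <- ed[i, "x2"] - ed[i, "x1"]; ry <- ed[i, "y2"] - ed[i, "y1"]
  sx <- ed[j, "x2"] - ed[j, "x1"]; sy <- ed[j, "y2"] - ed[j, "y1"]
  den <- rx * sy - ry * sx
  qpx <- ed[j, "x1"] - ed[i, "x1"]; qpy <- ed[j, "y1"] - ed[i, "y1"]
  ok <- den != 0
  tt <- ifelse(ok, (qpx * sy - qpy * sx) / den, NA_real_)
  uu <- ifelse(ok, (qpx * ry - qpy * rx) / den, NA_real_)
  hit <- ok & tt > 0 & tt < 1 & uu > 0 & uu < 1
  (ed[i, "x1"] + tt * rx)[hit]
}

# Covered y-measure (and optional y-moment) of the union / pairwise
# intersection of the edge sets, evaluated on the vertical line x = x0.
.measure_at <- function(x0, ed, op, nsets) {
  act <- (pmin(ed[, "x1"], ed[, "x2"]) < x0) & (x0 < pmax(ed[, "x1"], ed[, "x2"]))
  if (!any(act)) return(c(0, 0))
  e <- ed[act, , drop = FALSE]
  y <- e[, "y1"] + (x0 - e[, "x1"]) * (e[, "y2"] - e[, "y1"]) / (e[, "x2"] - e[, "x1"])
  key <- paste(e[, "set"], e[, "poly"])
  ys <- split(y, key)
  kset <- as.numeric(vapply(strsplit(names(ys), " "), `[`, "", 1L))
  starts <- list(); ends <- list(); sets <- list()
  for (k in seq_along(ys)) {
    v <- sort(ys[[k]])
    if (length(v) %% 2L == 1L) v <- v[-length(v)]  # defensive; cannot happen for valid rings
    if (length(v) == 0L) next
    odd <- seq(1L, length(v), by = 2L)
    starts[[length(starts) + 1L]] <- v[odd]
    ends[[length(ends) + 1L]] <- v[odd + 1L]
    sets[[length(sets) + 1L]] <- rep(kset[k], length(odd))
  }
  if (length(starts) == 0L) return(c(0, 0))
  s0 <- unlist(starts); e0 <- unlist(ends); st <- unlist(sets)
  ev_y <- c(s0, e0)
  ev_d <- c(rep(1, length(s0)), rep(-1, length(e0)))
  ev_s <- c(st, st)
  o <- order(ev_y)
  ev_y <- ev_y[o]; ev_d <- ev_d[o]; ev_s <- ev_s[o]
  nn <- length(ev_y)
  if (nn < 2L) return(c(0, 0))
  lo <- ev_y[-nn]; hi <- ev_y[-1L]
  cov1 <- cumsum(ev_d * (ev_s == 1))[-nn]
  covered <- cov1 >= 1
  if (op == "intersect") {
    cov2 <- cumsum(ev_d * (ev_s == 2))[-nn]
    covered <- covered & cov2 >= 1
  }
  len <- sum((hi - lo)[covered])
  ymom <- sum(((hi^2 - lo^2) / 2)[covered])
  c(len, ymom)
}

# Area (and optionally centroid moments) of a union or pairwise intersection
# of polygon sets, by slab decomposition. `edge_sets` is a list of one or two
# edge matrices as produced by .region_edges().
.slab_sweep <- function(edge_sets, op = c("union", "intersect"), moments = FALSE) {
  op <- match.arg(op)
  ed <- do.call(rbind, edge_sets)
  keep <- ed[, "x1"] != ed[, "x2"] | ed[, "y1"] != ed[, "y2"]
  ed <- ed[keep, , drop = FALSE]
  if (nrow(ed) == 0L) {
    return(if (moments) c(area = 0, mx = 0, my = 0) else c(area = 0))
  }
  xs <- sort(unique(c(ed[, "x1"], ed[, "x2"], .crossing_xs(ed))))
  nsets <- if (op == "intersect") 2L else 1L
  area <- 0; mx <- 0; my <- 0
  g <- 1 / (2 * sqrt(3))
  for (k in seq_len(length(xs) - 1L)) {
    xl <- xs[k]; xr <- xs[k + 1L]; w <- xr - xl
    if (w <= 0) next
    if (moments) {
      x1 <- (xl + xr) / 2 - w * g
      x2 <- (xl + xr) / 2 + w * g
      m1 <- .measure_at(x1, ed, op, nsets)
      m2 <- .measure_at(x2, ed, op, nsets)
      area <- area + w / 2 * (m1[1L] + m2[1L])
      mx <- mx + w / 2 * (x1 * m1[1L] + x2 * m2[1L])
      my <- my + w / 2 * (m1[2L] + m2[2L])
    } else {
      m <- .measure_at((xl + xr) / 2, ed, op, nsets)
      area <- area + w * m[1L]
    }
  }
  if (moments) c(area = area, mx = mx, my = my) else c(area = area)
}

#' Area of a planar region in square meters
#'
#' The measure of the union of the region's parts (parts may overlap, e.g.
#' after park merging); holes are honored via the even-odd rule.
#'
#' @param region a `planar_region`.
#' @return area in m^2.
#' @export
region_area <- function(region) {
  stopifnot(inherits(region, "planar_region"))
  # the shoelace shortcut would be wrong for self-intersecting rings
  # (even-odd measure != |signed area|), so always use the slab sweep
  unname(.slab_sweep(list(.region_edges(region)))["area"])
}

#' Centroid of a planar region
#'
#' @param region a `planar_region`.
#' @return numeric `c(x, y)` in meters (centroid of the union of parts).
#' @export
region_centroid <- function(region) {
  stopifnot(inherits(region, "planar_region"))
  m <- .slab_sweep(list(.region_edges(region)), moments = TRUE)
  if (m["area"] <= 0) stop("cannot compute centroid of a zero-area region")
  c(x = unname(m["mx"] / m["area"]), y = unname(m["my"] / m["area"]))
}

#' Area of the intersection of two regions, in square meters
#'
#' @param a,b `planar_region` objects.
#' @return area of (union of parts of a) intersected with (union of parts of b).
#' @export
region_intersection_area <- function(a, b) {
  stopifnot(inherits(a, "planar_region"), inherits(b, "planar_region"))
  if (!.bbox_overlap(.region_bbox(a), .region_bbox(b))) return(0)
  unname(.slab_sweep(list(.region_edges(a, set = 1L),
                          .region_edges(b, set = 2L)), op = "intersect")["area"])
}

#' Area of the union of several regions, in square meters
#'
#' @param regions list of `planar_region` objects.
#' @return area of the union.
#' @export
region_union_area <- function(regions) {
  stopifnot(is.list(regions), all(vapply(regions, inherits, TRUE, "planar_region")))
  if (length(regions) == 0L) return(0)
  eds <- vector("list", length(regions))
  off <- 0L
  for (k in seq_along(regions)) {
    eds[[k]] <- .region_edges(regions[[k]], set = 1L, poly_offset = off)
    off <- off + length(regions[[k]]$parts)
  }
  unname(.slab_sweep(eds)["area"])
}

.points_in_rings <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (r in rings) {
    n <- nrow(r)
    xi <- r[, 1L]; yi <- r[, 2L]
    xj <- r[c(2:n, 1L), 1L]; yj <- r[c(2:n, 1L), 2L]
    for (e in seq_len(n)) {
      crosses <- (yi[e] > py) != (yj[e] > py)
      if (any(crosses)) {
        xin <- (xj[e] - xi[e]) * (py[crosses] - yi[e]) / (yj[e] - yi[e]) + xi[e]
        flip <- px[crosses] < xin
        w <- which(crosses)[flip]
        inside[w] <- !inside[w]
      }
    }
  }
  inside
}

#' Test whether points fall inside a region
#'
#' Even-odd rule within each part; a point is inside the region if it is inside
#' any part. Points exactly on a boundary may land on either side (callers that
#' need deterministic boundary handling resolve ties themselves).
#'
#' @param pts two-column matrix of x, y (meters).
#' @param region a `planar_region`.
#' @return logical vector.
#' @export
region_contains <- function(pts, region) {
  stopifnot(inherits(region, "planar_region"))
  pts <- .as_points(pts)
  inside <- rep(FALSE, nrow(pts))
  for (part in region$parts) {
    inside <- inside | .points_in_rings(pts[, 1L], pts[, 2L], part)
  }
  inside
}

.as_points <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2L)
  pts <- as.matrix(pts)[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  pts
}

#' Euclidean distance from points to a region
#'
#' Zero for points inside the region (or any of its parts), otherwise the
#' minimum distance to the region's boundary segments.
#'
#' @param pts two-column matrix of x, y (meters).
#' @param region a `planar_region`.
#' @return numeric vector of distances in meters.
#' @export
region_distance <- function(pts, region) {
  stopifnot(inherits(region, "planar_region"))
  pts <- .as_points(pts)
  px <- pts[, 1L]; py <- pts[, 2L]
  d <- rep(Inf, length(px))
  for (part in region$parts) {
    for (r in part) {
      n <- nrow(r)
      xi <- r[, 1L]; yi <- r[, 2L]
      xj <- r[c(2:n, 1L), 1L]; yj <- r[c(2:n, 1L), 2L]
      for (e in seq_len(n)) {
        dx <- xj[e] - xi[e]; dy <- yj[e] - yi[e]
        len2 <- dx * dx + dy * dy
        tt <- if (len2 > 0) pmin(1, pmax(0, ((px - xi[e]) * dx + (py - yi[e]) * dy) / len2)) else 0
        qx <- xi[e] + tt * dx; qy <- yi[e] + tt * dy
        d <- pmin(d, sqrt((px - qx)^2 + (py - qy)^2))
      }
    }
  }
  d[region_contains(pts, region)] <- 0
  d
}

# Convenience constructors used by the synthetic generator and tests.

#' Axis-aligned rectangle region
#' @param xmin,ymin,xmax,ymax corner coordinates in meters.
#' @export
rect_region <- function(xmin, ymin, xmax, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  planar_region(cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax)))
}

#' Regular-polygon approximation of a disc
#' @param cx,cy center (meters); @param r radius (meters); @param n vertices.
#' @export
disc_region <- function(cx, cy, r, n = 64L) {
  stopifnot(r > 0, n >= 3L)
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  planar_region(cbind(cx + r * cos(th), cy + r * sin(th)))
}
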