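# Independent brute-force oracles. These deliberately use different
# algorithms/code paths from the package (winding number instead of ray
# casting, per-pair loops instead of vectorized slabs) so that agreement is a
# genuine dual-route check.

# winding-number point-in-ring (package uses even-odd ray casting)
oracle_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  wn <- 0L
  for (k in seq_len(n)) {
    x1 <- ring[k, 1]; y1 <- ring[k, 2]
    x2 <- ring[k %% n + 1L, 1]; y2 <- ring[k %% n + 1L, 2]
    cr <- (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1)
    if (y1 <= py) {
      if (y2 > py && cr > 0) wn <- wn + 1L
    } else {
      if (y2 <= py && cr < 0) wn <- wn - 1L
    }
  }
  wn != 0L
}

# even-odd across a part's rings (hole support), any-part for the region
oracle_region_contains <- function(px, py, region) {
  any(vapply(region$parts, function(part) {
    inside <- FALSE
    for (r in part) if (oracle_in_ring(px, py, r)) inside <- !inside
    inside
  }, TRUE))
}

oracle_region_distance <- function(px, py, region) {
  if (oracle_region_contains(px, py, region)) return(0)
  dmin <- Inf
  for (part in region$parts) for (r in part) {
    n <- nrow(r)
    for (k in seq_len(n)) {
      ax <- r[k, 1]; ay <- r[k, 2]
      bx <- r[k %% n + 1L, 1]; by <- r[k %% n + 1L, 2]
      vx <- bx - ax; vy <- by - ay
      L2 <- vx^2 + vy^2
      tt <- if (L2 > 0) max(0, min(1, ((px - ax) * vx + (py - ay) * vy) / L2)) else 0
      dmin <- min(dmin, sqrt((px - (ax + tt * vx))^2 + (py - (ay + tt * vy))^2))
    }
  }
  dmin
}

# Monte-Carlo area of a union of regions over a bbox
oracle_mc_area <- function(regions, n = 20000L) {
  bb <- sapply(regions, function(r) parkflux:::.region_bbox(r))
  xmin <- min(bb["xmin", ]); xmax <- max(bb["xmax", ])
  ymin <- min(bb["ymin", ]); ymax <- max(bb["ymax", ])
  px <- runif(n, xmin, xmax); py <- runif(n, ymin, ymax)
  hit <- vapply(seq_len(n), function(k) {
    any(vapply(regions, function(r) oracle_region_contains(px[k], py[k], r), TRUE))
  }, TRUE)
  mean(hit) * (xmax - xmin) * (ymax - ymin)
}

# brute-force incidence: double loop over (other-activity, park), home tract
# by winding-number containment
oracle_incidence <- function(trajectories, tracts, parks, radius_m) {
  tids <- vapply(tracts, function(t) t$tract_id, "")
  pids <- vapply(parks, function(p) p$park_id, "")
  X <- matrix(0L, length(tracts), length(parks),
              dimnames = list(tids, pids))
  homes <- trajectories[trajectories$kind == "home", ]
  ht <- vapply(seq_len(nrow(homes)), function(a) {
    hit <- which(vapply(tracts, function(t) {
      oracle_region_contains(homes$x[a], homes$y[a], t$region)
    }, TRUE))
    if (length(hit) == 0L) NA_character_ else tids[min(hit)]
  }, "")
  names(ht) <- homes$agent_id
  others <- trajectories[trajectories$kind == "other", ]
  for (q in seq_len(nrow(others))) {
    ti <- ht[others$agent_id[q]]
    if (is.na(ti)) next
    for (j in seq_along(parks)) {
      if (oracle_region_distance(others$x[q], others$y[q], parks[[j]]$region) <= radius_m) {
        X[ti, j] <- X[ti, j] + 1L
      }
    }
  }
  X
}

# dense double-loop Barber modularity
oracle_modularity <- function(X, ct, cp) {
  m <- sum(X)
  sT <- unname(rowSums(X)); sP <- unname(colSums(X))
  q <- 0
  for (i in seq_len(nrow(X))) for (j in seq_len(ncol(X))) {
    if (!is.na(ct[i]) && !is.na(cp[j]) && ct[i] == cp[j]) {
      q <- q + X[i, j] - sT[i] * sP[j] / m
    }
  }
  q / m
}

# all partitions of n items into at most kmax blocks (restricted growth)
oracle_enum_partitions <- function(n, kmax = 4L) {
  out <- list()
  rec <- function(prefix, mx) {
    i <- length(prefix) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(min(mx + 1L, kmax))) rec(c(prefix, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

oracle_best_Q <- function(X, kmax = 4L) {
  nT <- nrow(X); nP <- ncol(X)
  m <- sum(X)
  B <- X - outer(rowSums(X), colSums(X)) / m
  parts <- oracle_enum_partitions(nT + nP, kmax)
  max(vapply(parts, function(p) {
    sum(B * outer(p[seq_len(nT)], p[nT + seq_len(nP)], "==")) / m
  }, 0))
}

# plug-in MI by explicit loops over the joint table
oracle_mi <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  I <- 0
  for (x in ua) for (y in ub) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0) I <- I + pxy * log2(pxy / ((sum(a == x) / n) * (sum(b == y) / n)))
  }
  I
}

# random simple (star-convex) polygon around a center
rand_poly_region <- function(cx, cy, rmin, rmax, nv = 8L) {
  th <- sort(runif(nv, 0, 2 * pi))
  rr <- runif(nv, rmin, rmax)
  planar_region(cbind(cx + rr * cos(th), cy + rr * sin(th)))
}

rand_exposure_net <- function(nT, nP, lambda = 2, ensure_m = TRUE) {
  X <- matrix(rpois(nT * nP, lambda), nT, nP)
  if (ensure_m && sum(X) == 0) X[1, 1] <- 1
  exposure_network(X, sprintf("t%02d", seq_len(nT)), sprintf("p%02d", seq_len(nP)))
}
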