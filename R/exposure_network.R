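# Bipartite tract-park exposure network: activity/trajectory containers,
# buffer-based exposure assignment and incidence-matrix construction.

#' Trajectory activity table
#'
#' Validates a table of daily activities: one `home` row per agent plus zero or
#' more `other` rows (ordered; repeated identical points are distinct
#' activities). Work activities are out of scope and must not appear.
#'
#' @param df data.frame with columns `agent_id`, `kind` (`"home"`/`"other"`),
#'   `x`, `y` (planar meters) and optionally `slot` (10-minute index).
#' @return the validated data.frame with class `trajectory_set`.
#' @export
trajectory_set <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("agent_id", "kind", "x", "y") %in% names(df)))
  df$agent_id <- as.character(df$agent_id)
  if (!all(df$kind %in% c("home", "other"))) {
    stop("kind must be 'home' or 'other'")
  }
  if (!all(is.finite(df$x)) || !all(is.finite(df$y))) {
    stop("activity coordinates must be finite")
  }
  homes <- table(df$agent_id[df$kind == "home"])
  agents <- unique(df$agent_id)
  if (!setequal(names(homes), agents) || any(homes != 1L)) {
    stop("each agent must have exactly one home activity")
  }
  if (is.null(df$slot)) df$slot <- rep(NA_integer_, nrow(df))
  class(df) <- c("trajectory_set", "data.frame")
  df
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set: %d agent(s), %d other-activitie(s)>\n",
              length(unique(x$agent_id)), sum(x$kind == "other")))
  invisible(x)
}

# indices of parks within radius of each point; returns a two-column matrix
# (point index, park index)
.exposure_pairs <- function(pts, parks, radius_m) {
  pi_ <- integer(0); pj <- integer(0)
  if (nrow(pts) == 0L || length(parks) == 0L) {
    return(cbind(point = pi_, park = pj))
  }
  for (j in seq_along(parks)) {
    b <- .region_bbox(parks[[j]]$region)
    cand <- which(pts[, 1L] >= b["xmin"] - radius_m & pts[, 1L] <= b["xmax"] + radius_m &
                  pts[, 2L] >= b["ymin"] - radius_m & pts[, 2L] <= b["ymax"] + radius_m)
    if (length(cand) == 0L) next
    d <- region_distance(pts[cand, , drop = FALSE], parks[[j]]$region)
    hit <- cand[d <= radius_m]
    pi_ <- c(pi_, hit); pj <- c(pj, rep(j, length(hit)))
  }
  cbind(point = pi_, park = pj)
}

#' Parks exposed to an activity location
#'
#' A park is exposed if it intersects the uncertainty circle of radius
#' `radius_m` around the point, i.e. if the euclidean distance from the point
#' to the park polygon is at most `radius_m` (a point inside a park has
#' distance 0).
#'
#' @param point length-2 numeric (x, y in meters).
#' @param parks list of [park()] objects (disjoint after merging).
#' @param radius_m exposure radius in meters (default 200, the grid
#'   half-resolution of the trajectory model).
#' @return character vector of exposed park ids (possibly empty).
#' @export
exposed_parks <- function(point, parks, radius_m = 200) {
  stopifnot(radius_m > 0)
  pairs <- .exposure_pairs(.as_points(point), parks, radius_m)
  park_ids(parks)[pairs[, "park"]]
}

#' Exposure network container
#'
#' @param X sparse (or dense) non-negative integer matrix, rows = tracts,
#'   columns = parks.
#' @param tract_ids,park_ids row/column ids.
#' @param radius_m exposure radius used to build the network.
#' @param report optional list of construction counts.
#' @return object of class `exposure_network`.
#' @export
exposure_network <- function(X, tract_ids, park_ids, radius_m = 200,
                             report = list()) {
  X <- methods::as(methods::as(Matrix::Matrix(X, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (any(X@x < 0) || any(X@x != round(X@x))) {
    stop("incidence entries must be non-negative integers")
  }
  stopifnot(nrow(X) == length(tract_ids), ncol(X) == length(park_ids))
  dimnames(X) <- list(tract_ids, park_ids)
  structure(list(X = X, tract_ids = as.character(tract_ids),
                 park_ids = as.character(park_ids),
                 radius_m = radius_m, report = report),
            class = "exposure_network")
}

#' @export
print.exposure_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf("<exposure_network: %d tracts x %d parks, L = %d, m = %d, r = %g m>\n",
              s$N_T, s$N_P, s$L, s$m, x$radius_m))
  invisible(x)
}

#' Build the tract-park incidence matrix from trajectories
#'
#' Entry `X[i, j]` counts the other-type activities whose agent's home lies in
#' tract i and whose uncertainty circle (radius `radius_m`) intersects park j.
#' One activity exposed to k parks contributes 1 to each of the k entries.
#' Agents whose home falls outside every tract are dropped and counted in the
#' report.
#'
#' @param trajectories a [trajectory_set()].
#' @param tracts list of [tract()] objects (interior-disjoint).
#' @param parks list of [park()] objects (merged/disjoint).
#' @param radius_m exposure radius in meters (default 200).
#' @return an [exposure_network()]; `$report` holds agent/activity counts
#'   (`n_agents`, `n_agents_dropped`, `n_other`, `traj_with_exposure`,
#'   `oa_with_exposure`).
#' @export
build_incidence <- function(trajectories, tracts, parks, radius_m = 200) {
  trajectories <- trajectory_set(as.data.frame(trajectories))
  stopifnot(radius_m > 0)
  homes <- trajectories[trajectories$kind == "home", , drop = FALSE]
  home_tract <- assign_home_tract(cbind(homes$x, homes$y), tracts)
  agent_tract <- stats::setNames(home_tract, homes$agent_id)
  kept_agents <- names(agent_tract)[!is.na(agent_tract)]

  others <- trajectories[trajectories$kind == "other", , drop = FALSE]
  others_kept <- others[others$agent_id %in% kept_agents, , drop = FALSE]

  tids <- tract_ids(tracts)
  pids <- park_ids(parks)
  pairs <- .exposure_pairs(cbind(others_kept$x, others_kept$y), parks, radius_m)
  ti <- match(agent_tract[others_kept$agent_id[pairs[, "point"]]], tids)
  X <- Matrix::sparseMatrix(i = ti, j = pairs[, "park"], x = 1,
                            dims = c(length(tids), length(pids)))
  exposed_points <- unique(pairs[, "point"])
  report <- list(
    n_agents = length(agent_tract),
    n_agents_dropped = sum(is.na(agent_tract)),
    n_other = nrow(others),
    n_other_kept = nrow(others_kept),
    oa_with_exposure = length(exposed_points),
    traj_with_exposure = length(unique(others_kept$agent_id[exposed_points]))
  )
  exposure_network(X, tids, pids, radius_m = radius_m, report = report)
}

#' Summary of an exposure network
#'
#' Node, link and weight counts with their ratios: number of tracts `N_T`,
#' parks `N_P`, links `L`, total weight `m`, mean link weight `m/L`, mean park
#' demand `m/N_P`, mean tract exposure `m/N_T` and mean tract degree `L/N_T`.
#' Ratios with a zero denominator are reported as `NA`.
#'
#' @param net an [exposure_network()], or `NULL` if raw counts are given.
#' @param N_T,N_P,L,m raw counts (used when `net` is NULL), e.g. published
#'   totals for a network that cannot be rebuilt.
#' @return list of class `network_summary`.
#' @export
network_summary <- function(net = NULL, N_T = NULL, N_P = NULL, L = NULL, m = NULL) {
  if (!is.null(net)) {
    stopifnot(inherits(net, "exposure_network"))
    N_T <- nrow(net$X); N_P <- ncol(net$X)
    L <- Matrix::nnzero(net$X); m <- sum(net$X)
  }
  rat <- function(a, b) if (b > 0) a / b else NA_real_
  structure(list(N_T = N_T, N_P = N_P, L = L, m = m,
                 m_over_L = rat(m, L), m_over_NP = rat(m, N_P),
                 m_over_NT = rat(m, N_T), L_over_NT = rat(L, N_T)),
            class = "network_summary")
}

#' Paper-style integer/decimal renderings of summary ratios
#'
#' Published tables mix truncation and nearest rounding; both renderings are
#' exposed. Mean link weight is rendered to 2 decimals, the other ratios to
#' integers.
#'
#' @param s a [network_summary()].
#' @param mode `"truncate"` or `"nearest"`.
#' @return list of rendered ratios.
#' @export
render_summary <- function(s, mode = c("truncate", "nearest")) {
  mode <- match.arg(mode)
  int <- function(x) {
    if (is.na(x)) return(NA_real_)
    if (mode == "truncate") trunc(x) else round(x)
  }
  dec2 <- function(x) {
    if (is.na(x)) return(NA_real_)
    if (mode == "truncate") trunc(x * 100) / 100 else round(x, 2)
  }
  list(m_over_L = dec2(s$m_over_L), m_over_NP = int(s$m_over_NP),
       m_over_NT = int(s$m_over_NT), L_over_NT = int(s$L_over_NT))
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("N_T = %d, N_P = %d, L = %d, m = %d\n", x$N_T, x$N_P, x$L, x$m))
  cat(sprintf("m/L = %.3f, m/N_P = %.1f, m/N_T = %.1f, L/N_T = %.1f\n",
              x$m_over_L, x$m_over_NP, x$m_over_NT, x$L_over_NT))
  invisible(x)
}
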