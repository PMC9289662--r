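# Node-level network metrics: strengths (exposure and demand), weighted
# neighbor averages, predominant-group labeling, homophily and group
# crosstabs.

#' Tract strengths (park exposure)
#'
#' Row sums of the incidence matrix: the number of potential park visits made
#' by residents of each tract during other-type activities.
#'
#' @param net an [exposure_network()].
#' @return named integer-valued numeric vector `s^T`.
#' @export
tract_strength <- function(net) {
  stopifnot(inherits(net, "exposure_network"))
  stats::setNames(Matrix::rowSums(net$X), net$tract_ids)
}

#' Park strengths (park demand)
#'
#' Column sums of the incidence matrix: the number of potential visits each
#' park receives, i.e. other-activities within the exposure radius of its
#' border.
#'
#' @param net an [exposure_network()].
#' @return named integer-valued numeric vector `s^P`.
#' @export
park_strength <- function(net) {
  stopifnot(inherits(net, "exposure_network"))
  stats::setNames(Matrix::colSums(net$X), net$park_ids)
}

#' Visit-weighted neighbor average of a node attribute
#'
#' For a park attribute beta, each tract i gets
#' `(1/s^T_i) * sum_j X[i,j] beta_j` (and symmetrically for a tract attribute
#' alpha averaged onto parks). Nodes with zero strength have no neighbors and
#' get `NA`, never a silent 0.
#'
#' @param net an [exposure_network()].
#' @param values numeric attribute vector.
#' @param side side the attribute lives on: `"park"` (averaged onto tracts) or
#'   `"tract"` (averaged onto parks).
#' @return named numeric vector on the opposite side, `NA` for zero-strength
#'   nodes.
#' @export
neighbor_weighted_average <- function(net, values, side = c("park", "tract")) {
  side <- match.arg(side)
  stopifnot(inherits(net, "exposure_network"))
  if (side == "park") {
    stopifnot(length(values) == ncol(net$X))
    if (anyNA(values)) stop("attribute values must not be missing")
    s <- Matrix::rowSums(net$X)
    num <- as.numeric(net$X %*% values)
    out <- ifelse(s > 0, num / s, NA_real_)
    stats::setNames(out, net$tract_ids)
  } else {
    stopifnot(length(values) == nrow(net$X))
    if (anyNA(values)) stop("attribute values must not be missing")
    s <- Matrix::colSums(net$X)
    num <- as.numeric(Matrix::crossprod(net$X, values))
    out <- ifelse(s > 0, num / s, NA_real_)
    stats::setNames(out, net$park_ids)
  }
}

.argmax_group <- function(values, groups) {
  # first-in-group-order argmax with tie flag
  mx <- max(values)
  winners <- groups[values == mx]
  list(label = winners[1L], tie = length(winners) > 1L)
}

#' Label tracts by predominant racial/ethnic group
#'
#' Argmax of the population counts over all five groups; ties resolve to the
#' earliest group in [group_order()] with `tie_flag` set. A tract labeled
#' `Other` would contradict the expected data shape and triggers a warning.
#'
#' @param tracts list of [tract()] objects.
#' @return data.frame with columns `tract_id`, `label`, `tie_flag`.
#' @export
label_tracts <- function(tracts) {
  res <- lapply(tracts, function(t) .argmax_group(t$group_counts[group_order()], group_order()))
  labels <- vapply(res, function(r) r$label, "")
  if (any(labels == "Other")) {
    warning(sprintf("%d tract(s) labeled 'Other'; expected predominant groups only",
                    sum(labels == "Other")))
  }
  data.frame(tract_id = tract_ids(tracts), label = labels,
             tie_flag = vapply(res, function(r) r$tie, TRUE),
             stringsAsFactors = FALSE)
}

#' Per-tract group proportions
#'
#' @param tracts list of [tract()] objects.
#' @return matrix, one row per tract, columns in [group_order()]; proportions
#'   sum to 1 per row. Zero-population tracts are an error.
#' @export
tract_group_fractions <- function(tracts) {
  m <- t(vapply(tracts, function(t) t$group_counts[group_order()], numeric(5L)))
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    stop(sprintf("tract(s) with zero population: %s",
                 paste(tract_ids(tracts)[tot <= 0], collapse = ", ")))
  }
  m <- m / tot
  rownames(m) <- tract_ids(tracts)
  colnames(m) <- group_order()
  m
}

#' Label parks by predominant group of their potential visitors
#'
#' Each park's visitor composition is the visit-weighted neighbor average of
#' its linked tracts' group fractions; the label is the argmax over the four
#' named groups (White, Black, Asian, Hispanic) - the Other fraction is
#' carried but never wins. Zero-strength parks are unlabeled (`NA`).
#'
#' @param net an [exposure_network()].
#' @param tracts list of [tract()] objects aligned with `net$tract_ids`.
#' @return data.frame with columns `park_id`, `label`, `tie_flag`, plus one
#'   proportion column per group.
#' @export
label_parks <- function(net, tracts) {
  stopifnot(identical(tract_ids(tracts), net$tract_ids))
  frac <- tract_group_fractions(tracts)
  props <- vapply(group_order(), function(g) {
    neighbor_weighted_average(net, frac[, g], side = "tract")
  }, numeric(length(net$park_ids)))
  if (length(net$park_ids) == 1L) props <- matrix(props, nrow = 1L,
                                                  dimnames = list(net$park_ids, group_order()))
  named <- setdiff(group_order(), "Other")
  lab <- rep(NA_character_, nrow(props))
  tie <- rep(NA, nrow(props))
  ok <- !is.na(props[, 1L])
  for (k in which(ok)) {
    r <- .argmax_group(props[k, named], named)
    lab[k] <- r$label; tie[k] <- r$tie
  }
  out <- data.frame(park_id = net$park_ids, label = lab, tie_flag = tie,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(props))
}

#' Label homophily of tracts and parks
#'
#' For each node, the visit-weighted fraction of its cross-side neighbors
#' sharing its predominant-group label: `h^T_i = (1/s^T_i) sum_j X[i,j]
#' delta(g^T_i, g^P_j)` and symmetrically for parks. Zero-strength or
#' unlabeled nodes get `NA`.
#'
#' @param net an [exposure_network()].
#' @param tract_labels,park_labels character vectors aligned to the network's
#'   tract/park order (or the data.frames from [label_tracts()] /
#'   [label_parks()]).
#' @return list with named vectors `h_tract` and `h_park` in `[0, 1]`.
#' @export
homophily <- function(net, tract_labels, park_labels) {
  stopifnot(inherits(net, "exposure_network"))
  if (is.data.frame(tract_labels)) tract_labels <- tract_labels$label
  if (is.data.frame(park_labels)) park_labels <- park_labels$label
  stopifnot(length(tract_labels) == nrow(net$X),
            length(park_labels) == ncol(net$X))
  Xt <- methods::as(net$X, "TsparseMatrix")
  i <- Xt@i + 1L; j <- Xt@j + 1L; w <- Xt@x
  same <- !is.na(tract_labels[i]) & !is.na(park_labels[j]) &
    tract_labels[i] == park_labels[j]
  sT <- Matrix::rowSums(net$X); sP <- Matrix::colSums(net$X)
  numT <- numeric(nrow(net$X)); numP <- numeric(ncol(net$X))
  if (any(same)) {
    aggT <- rowsum(w[same], i[same])
    numT[as.integer(rownames(aggT))] <- aggT[, 1L]
    aggP <- rowsum(w[same], j[same])
    numP[as.integer(rownames(aggP))] <- aggP[, 1L]
  }
  hT <- ifelse(sT > 0 & !is.na(tract_labels), numT / sT, NA_real_)
  hP <- ifelse(sP > 0 & !is.na(park_labels), numP / sP, NA_real_)
  list(h_tract = stats::setNames(hT, net$tract_ids),
       h_park = stats::setNames(hP, net$park_ids))
}

#' Assign parks to the tract-group region containing them
#'
#' Rule `"centroid"` assigns a park to the tract containing its centroid;
#' `"largest-overlap"` assigns it to the tract with which it shares the most
#' area. Parks matching no tract get `NA`.
#'
#' @param parks list of [park()] objects.
#' @param tracts list of [tract()] objects.
#' @param rule `"centroid"` (default) or `"largest-overlap"`.
#' @return character vector of tract ids, one per park.
#' @export
assign_parks_to_tracts <- function(parks, tracts, rule = c("centroid", "largest-overlap")) {
  rule <- match.arg(rule)
  if (rule == "centroid") {
    cent <- t(vapply(parks, function(p) region_centroid(p$region), numeric(2L)))
    assign_home_tract(cent, tracts)
  } else {
    tids <- tract_ids(tracts)
    vapply(parks, function(p) {
      ov <- vapply(tracts, function(t) region_intersection_area(p$region, t$region), 0)
      if (max(ov) <= 0) return(NA_character_)
      # largest overlap, smallest tract id on exact ties
      best <- which(ov == max(ov))
      tids[best[order(tids[best])[1L]]]
    }, "")
  }
}

#' Group composition crosstabs
#'
#' Two tables mirroring published summaries: (i) per-group tract counts, % of
#' city area, park counts and % of total park area; (ii) for the set of tracts
#' of each group, the row-normalized percentage of contained parks by park
#' label plus the total count of contained parks.
#'
#' @param tracts,parks lists of [tract()] / [park()] objects.
#' @param tract_labels,park_labels outputs of [label_tracts()] /
#'   [label_parks()] (or aligned character vectors).
#' @param assignment_rule how parks map to tract regions; see
#'   [assign_parks_to_tracts()].
#' @return list with data.frames `by_group` and `parks_within_tracts`.
#' @export
group_crosstabs <- function(tracts, parks, tract_labels, park_labels,
                            assignment_rule = c("centroid", "largest-overlap")) {
  assignment_rule <- match.arg(assignment_rule)
  if (is.data.frame(tract_labels)) tract_labels <- tract_labels$label
  if (is.data.frame(park_labels)) park_labels <- park_labels$label
  named <- setdiff(group_order(), "Other")
  t_area <- vapply(tracts, function(t) t$area_km2, 0)
  p_area <- park_areas_km2(parks)
  by_group <- data.frame(
    group = named,
    n_tracts = vapply(named, function(g) sum(tract_labels == g, na.rm = TRUE), 0),
    pct_city_area = vapply(named, function(g) {
      100 * sum(t_area[which(tract_labels == g)]) / sum(t_area)
    }, 0),
    n_parks = vapply(named, function(g) sum(park_labels == g, na.rm = TRUE), 0),
    pct_park_area = vapply(named, function(g) {
      100 * sum(p_area[which(park_labels == g)]) / sum(p_area)
    }, 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  host <- assign_parks_to_tracts(parks, tracts, rule = assignment_rule)
  host_group <- tract_labels[match(host, tract_ids(tracts))]
  rows <- lapply(named, function(g) {
    inside <- which(host_group == g & !is.na(park_labels))
    tot <- length(inside)
    pct <- vapply(named, function(pg) {
      if (tot == 0L) 0 else 100 * sum(park_labels[inside] == pg) / tot
    }, 0)
    c(stats::setNames(pct, paste0("pct_", named)), total_parks = tot)
  })
  parks_within <- data.frame(tract_group = named, do.call(rbind, rows),
                             row.names = NULL, stringsAsFactors = FALSE)
  list(by_group = by_group, parks_within_tracts = parks_within)
}

#' Per-group homophily summary (mean and sd)
#'
#' @param h output of [homophily()].
#' @param tract_labels,park_labels aligned label vectors or label data.frames.
#' @return data.frame with group, side, mean, sd and n (NA values excluded).
#' @export
homophily_summary <- function(h, tract_labels, park_labels) {
  if (is.data.frame(tract_labels)) tract_labels <- tract_labels$label
  if (is.data.frame(park_labels)) park_labels <- park_labels$label
  named <- setdiff(group_order(), "Other")
  one <- function(vals, labs, side) {
    do.call(rbind, lapply(named, function(g) {
      v <- vals[which(labs == g)]
      v <- v[!is.na(v)]
      data.frame(group = g, side = side, n = length(v),
                 mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  rbind(one(h$h_tract, tract_labels, "tract"),
        one(h$h_park, park_labels, "park"))
}
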