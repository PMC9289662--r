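# End-to-end orchestration: merge -> build -> metrics -> communities ->
# distributions, assembled into a report bundle mirroring the standard
# summary tables.

#' Total area of urban parks
#'
#' Urban parks are parks smaller than the threshold (default 1 km^2),
#' separating neighborhood-scale green space from large reserves.
#'
#' @param parks list of [park()] objects.
#' @param threshold_km2 area threshold (exclusive), km^2.
#' @return total area in km^2 of parks with area below the threshold.
#' @export
urban_park_area <- function(parks, threshold_km2 = 1) {
  a <- park_areas_km2(parks)
  sum(a[a < threshold_km2])
}

#' Run configuration
#'
#' @param radius_m exposure radius, meters (default 200: the half-resolution
#'   of the 400 m activity grid).
#' @param urban_park_threshold_km2 urban-park area threshold (default 1).
#' @param n_permutations permutations for the mutual-information null
#'   (default 5000).
#' @param seed integer seed driving community detection and the permutation
#'   null.
#' @param assignment_rule park-to-tract-region rule for crosstabs.
#' @param rounding paper-style ratio rendering mode.
#' @return list of class `run_config`.
#' @export
run_config <- function(radius_m = 200, urban_park_threshold_km2 = 1,
                       n_permutations = 5000L, seed = 1L,
                       assignment_rule = c("centroid", "largest-overlap"),
                       rounding = c("truncate", "nearest")) {
  stopifnot(radius_m > 0, n_permutations >= 1L)
  structure(list(radius_m = radius_m,
                 urban_park_threshold_km2 = urban_park_threshold_km2,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 assignment_rule = match.arg(assignment_rule),
                 rounding = match.arg(rounding)),
            class = "run_config")
}

#' Run the full exposure-network pipeline
#'
#' Merges overlapping parks, builds the tract-park incidence network from the
#' trajectories, computes strengths, labels, homophily, crosstabs, community
#' structure with its modularity, mutual information between group labels and
#' community labels (with a permutation null), and distributional summaries.
#' Deterministic given the config seed.
#'
#' @param tracts list of [tract()] objects.
#' @param parks list of [park()] objects (merged internally).
#' @param trajectories a [trajectory_set()].
#' @param config a [run_config()].
#' @param out_dir optional directory; if given, all report components are
#'   written there (CSV/JSON/MTX/GeoJSON).
#' @return a list report bundle (class `parkflux_report`).
#' @export
run_pipeline <- function(tracts, parks, trajectories, config = run_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  n_parks_in <- length(parks)
  merged <- merge_overlapping_parks(parks)
  net <- build_incidence(trajectories, tracts, merged,
                         radius_m = config$radius_m)
  summ <- network_summary(net)
  sT <- tract_strength(net); sP <- park_strength(net)

  t_labels <- label_tracts(tracts)
  p_labels <- label_parks(net, tracts)
  h <- homophily(net, t_labels, p_labels)
  h_summary <- homophily_summary(h, t_labels, p_labels)
  crosstabs <- group_crosstabs(tracts, merged, t_labels, p_labels,
                               assignment_rule = config$assignment_rule)

  partition <- detect_communities(net, seed = config$seed)
  mi_tract <- permutation_null_mi(t_labels$label, partition$c_tract,
                                  n = config$n_permutations,
                                  seed = config$seed)
  mi_park <- permutation_null_mi(p_labels$label, partition$c_park,
                                 n = config$n_permutations,
                                 seed = config$seed + 1L)

  mtd <- median_home_other_distance(trajectories, tracts)
  mvpa <- mean_visited_park_area(net, merged)
  t_area <- vapply(tracts, function(t) t$area_km2, 0)

  table1 <- list(
    population = sum(vapply(tracts, function(t) sum(t$group_counts), 0)),
    city_area_km2 = sum(t_area),
    n_tracts = length(tracts),
    park_area_km2 = sum(park_areas_km2(merged)),
    urban_park_area_km2 = urban_park_area(merged, config$urban_park_threshold_km2),
    n_parks_input = n_parks_in,
    n_parks = length(merged),
    n_urban_parks = sum(park_areas_km2(merged) < config$urban_park_threshold_km2),
    n_trajectories = net$report$n_agents,
    n_trajectories_dropped = net$report$n_agents_dropped,
    n_other_activities = net$report$n_other,
    mtd_to_oa_km = list(mean = attr(mtd, "city_mean_km"),
                        sd = attr(mtd, "city_sd_km")),
    traj_with_park_exposure = net$report$traj_with_exposure,
    oa_with_park_exposure = net$report$oa_with_exposure
  )
  report <- structure(list(
    config = config,
    table1 = table1,
    summary = summ,
    summary_rendered = render_summary(summ, mode = config$rounding),
    network = net,
    parks_merged = merged,
    tract_labels = t_labels,
    park_labels = p_labels,
    homophily = h,
    homophily_summary = h_summary,
    crosstabs = crosstabs,
    partition = partition,
    mi_tract = mi_tract,
    mi_park = mi_park,
    tract_strength = sT,
    park_strength = sP,
    mean_visited_park_area_km2 = mvpa,
    median_home_other_distance_km = mtd,
    park_area_fraction = park_area_fraction(tracts, merged)
  ), class = "parkflux_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.parkflux_report <- function(x, ...) {
  cat("parkflux report\n")
  cat(sprintf("  tracts %d, parks %d (from %d input polygons)\n",
              x$table1$n_tracts, x$table1$n_parks, x$table1$n_parks_input))
  cat(sprintf("  L = %d, m = %d, Q = %.4f (%d communities)\n",
              x$summary$L, x$summary$m, x$partition$Q, x$partition$k))
  cat(sprintf("  MI(tract groups, communities) = %.4g bits (null %.4g +- %.4g)\n",
              x$mi_tract$observed_bits, x$mi_tract$null_mean_bits,
              x$mi_tract$null_sd_bits))
  invisible(x)
}

#' Write a report bundle to a directory
#'
#' @param report output of [run_pipeline()].
#' @param out_dir directory (created if needed).
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  jsonlite::write_json(report$table1, fp("table1.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(c(unclass(report$summary),
                         list(rendered = report$summary_rendered)),
                       fp("network_summary.json"), auto_unbox = TRUE, digits = NA)
  write_network_mtx(report$network, fp("network.mtx"))
  write_parks_geojson(report$parks_merged, fp("parks_merged.geojson"))
  utils::write.csv(report$tract_labels, fp("tract_labels.csv"), row.names = FALSE)
  utils::write.csv(report$park_labels, fp("park_labels.csv"), row.names = FALSE)
  utils::write.csv(report$crosstabs$by_group, fp("groups_by_city.csv"),
                   row.names = FALSE)
  utils::write.csv(report$crosstabs$parks_within_tracts,
                   fp("parks_within_tract_groups.csv"), row.names = FALSE)
  utils::write.csv(report$homophily_summary, fp("homophily_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(
    node_id = c(report$network$tract_ids, report$network$park_ids),
    side = c(rep("tract", length(report$network$tract_ids)),
             rep("park", length(report$network$park_ids))),
    community = c(report$partition$c_tract, report$partition$c_park)),
    fp("partition.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    tract = unclass(report$mi_tract)[c("observed_bits", "null_mean_bits",
                                       "null_sd_bits", "exceedance",
                                       "n_permutations")],
    park = unclass(report$mi_park)[c("observed_bits", "null_mean_bits",
                                     "null_sd_bits", "exceedance",
                                     "n_permutations")],
    Q = report$partition$Q, k = report$partition$k),
    fp("communities_mi.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(
    tract_id = names(report$tract_strength),
    strength = as.numeric(report$tract_strength),
    mean_visited_park_area_km2 = as.numeric(report$mean_visited_park_area_km2),
    median_home_other_distance_km = as.numeric(report$median_home_other_distance_km),
    park_area_fraction = as.numeric(report$park_area_fraction)),
    fp("tract_metrics.csv"), row.names = FALSE)
  utils::write.csv(data.frame(
    park_id = names(report$park_strength),
    strength = as.numeric(report$park_strength)),
    fp("park_metrics.csv"), row.names = FALSE)
  invisible(out_dir)
}
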