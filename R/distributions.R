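# Distributional summaries: log-binned densities, log-normal fits, mean
# visited-park area and median home-to-other travel distance.

#' Log-binned density of a positive-valued sample
#'
#' Histogram on geometrically spaced bins from the smallest to the largest
#' positive value; bins are left-closed, right-open except the last (closed).
#' Zeros and negatives are excluded and counted. Density is per unit of the
#' original scale, normalized so the integral equals the fraction of values
#' included.
#'
#' @param values numeric sample.
#' @param n_bins number of bins (>= 2).
#' @return object of class `log_binned_density` with `bin_edges`, `counts`,
#'   `density` and `n_zero_excluded`.
#' @export
log_binned_density <- function(values, n_bins = 20L) {
  stopifnot(n_bins >= 2L)
  values <- values[!is.na(values)]
  pos <- values[values > 0]
  n_excl <- length(values) - length(pos)
  if (length(pos) == 0L) stop("no positive values to bin")
  lo <- min(pos); hi <- max(pos)
  if (lo == hi) { lo <- lo * (1 - 1e-9); hi <- hi * (1 + 1e-9) }
  edges <- exp(seq(log(lo), log(hi), length.out = n_bins + 1L))
  idx <- findInterval(pos, edges, rightmost.closed = TRUE, left.open = FALSE)
  idx[idx > n_bins] <- n_bins
  counts <- tabulate(idx, nbins = n_bins)
  widths <- diff(edges)
  density <- counts / (length(values) * widths)
  structure(list(bin_edges = edges, counts = counts, density = density,
                 n_zero_excluded = n_excl, n = length(values)),
            class = "log_binned_density")
}

#' @export
print.log_binned_density <- function(x, ...) {
  cat(sprintf("<log_binned_density: %d bins over [%.4g, %.4g], %d value(s), %d excluded>\n",
              length(x$counts), x$bin_edges[1L], x$bin_edges[length(x$bin_edges)],
              x$n, x$n_zero_excluded))
  invisible(x)
}

#' Maximum-likelihood log-normal fit
#'
#' Fits `ln(v) ~ Normal(mu_log, sigma_log)` by maximum likelihood and derives
#' the natural-scale mean and sd of the fitted log-normal
#' (`mu_natural = exp(mu_log + sigma_log^2 / 2)`). Because "natural scale" is
#' ambiguous, the geometric mean `exp(mu_log)` is also reported.
#'
#' @param values strictly positive sample, n >= 3, not all equal.
#' @return object of class `lognormal_fit`: `mu_log`, `sigma_log`,
#'   `mu_natural`, `sigma_natural`, `exp_mu_log`, `n`.
#' @export
fit_lognormal <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3L) stop("need at least 3 values")
  if (any(values <= 0)) stop("all values must be positive")
  lv <- log(values)
  mu <- mean(lv)
  sigma <- sqrt(mean((lv - mu)^2))
  if (sigma <= 0) stop("degenerate sample: all values equal")
  mu_nat <- exp(mu + sigma^2 / 2)
  sd_nat <- mu_nat * sqrt(exp(sigma^2) - 1)
  structure(list(mu_log = mu, sigma_log = sigma, mu_natural = mu_nat,
                 sigma_natural = sd_nat, exp_mu_log = exp(mu),
                 n = length(values)),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf("<lognormal_fit: mu_log = %.4g, sigma_log = %.4g (natural mean %.4g, sd %.4g), n = %d>\n",
              x$mu_log, x$sigma_log, x$mu_natural, x$sigma_natural, x$n))
  invisible(x)
}

#' Mean area of the potentially visited parks, per tract
#'
#' The visit-weighted neighbor average of park areas: the typical size of a
#' park that residents of each tract are exposed to. `NA` for tracts with no
#' exposure.
#'
#' @param net an [exposure_network()].
#' @param parks list of [park()] objects aligned with `net$park_ids`.
#' @return named numeric vector, km^2 per tract.
#' @export
mean_visited_park_area <- function(net, parks) {
  stopifnot(identical(park_ids(parks), net$park_ids))
  neighbor_weighted_average(net, park_areas_km2(parks), side = "park")
}

#' Median home-to-other travel distance, per tract
#'
#' For each trajectory, the median euclidean distance between its home and
#' each of its other-type activities; per tract, the median of those
#' trajectory medians over trajectories homed there. Trajectories with no
#' other-activities (or homes outside all tracts) are excluded and counted.
#'
#' @param trajectories a [trajectory_set()].
#' @param tracts list of [tract()] objects.
#' @return named numeric vector of km per tract (`NA` where no trajectory
#'   qualifies), with attributes `n_excluded_no_other`,
#'   `n_excluded_no_tract`, `city_mean_km` and `city_sd_km` (mean +- sd over
#'   tract values).
#' @export
median_home_other_distance <- function(trajectories, tracts) {
  trajectories <- trajectory_set(as.data.frame(trajectories))
  homes <- trajectories[trajectories$kind == "home", , drop = FALSE]
  home_tract <- assign_home_tract(cbind(homes$x, homes$y), tracts)
  hx <- stats::setNames(homes$x, homes$agent_id)
  hy <- stats::setNames(homes$y, homes$agent_id)
  tr_of <- stats::setNames(home_tract, homes$agent_id)
  others <- trajectories[trajectories$kind == "other", , drop = FALSE]
  d_km <- sqrt((others$x - hx[others$agent_id])^2 +
               (others$y - hy[others$agent_id])^2) / 1000
  med_by_agent <- vapply(split(d_km, others$agent_id), stats::median, 0)
  agents_with_other <- names(med_by_agent)
  n_no_other <- length(hx) - length(agents_with_other)
  keep <- !is.na(tr_of[agents_with_other])
  n_no_tract <- sum(!keep)
  med_kept <- med_by_agent[keep]
  tract_of_kept <- tr_of[agents_with_other][keep]
  out <- stats::setNames(rep(NA_real_, length(tracts)), tract_ids(tracts))
  if (length(med_kept) > 0L) {
    agg <- vapply(split(med_kept, tract_of_kept), stats::median, 0)
    out[names(agg)] <- agg
  }
  v <- out[!is.na(out)]
  attr(out, "n_excluded_no_other") <- n_no_other
  attr(out, "n_excluded_no_tract") <- n_no_tract
  attr(out, "city_mean_km") <- if (length(v)) mean(v) else NA_real_
  attr(out, "city_sd_km") <- if (length(v) > 1L) stats::sd(v) else NA_real_
  out
}
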