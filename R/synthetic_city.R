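# Seedable synthetic city generator: grid tracts with Dirichlet demographic
# mixtures, log-normally sized parks (even or clustered placement), and
# home/other daily trajectories with Poisson activity counts and
# exponential-tailed displacements snapped to a 400 m grid.

#' Synthetic city configuration
#'
#' Defaults emulate the data shapes the analysis consumes at desk scale: a
#' 6 x 6 km tract grid with ~4000 residents per tract (metropolitan tracts
#' average ~4500), about one other-type activity per daily trajectory (the
#' observed OA-per-trajectory ratio is close to 1), 400 m location
#' granularity with a 200 m jitter, and log-normal park areas.
#'
#' @param grid_rows,grid_cols tract grid dimensions.
#' @param tract_side_m side of each square tract, meters.
#' @param n_parks number of parks to place.
#' @param park_area_mu_log,park_area_sigma_log log-normal parameters of park
#'   area in km^2 (defaults: median 0.05 km^2, sigma 1 - neighborhood-scale
#'   urban parks).
#' @param park_placement `"even"` (uniform over the city, Boston-like) or
#'   `"clustered"` (Gaussian clusters, Los-Angeles-like).
#' @param n_agents number of daily trajectories.
#' @param mean_other_activities Poisson mean of other-activities per agent.
#' @param displacement_scale_km scale of the exponential home-to-other radial
#'   displacement, km.
#' @param segregation_alpha Dirichlet concentration of per-tract group
#'   mixtures around the global mixture; small = segregated.
#' @param population_per_tract residents per tract.
#' @param global_mix named global group proportions over [group_order()].
#' @param seed RNG seed; all generation is deterministic given it.
#' @return list of class `synthetic_city_config`.
#' @export
synthetic_city_config <- function(grid_rows = 6L, grid_cols = 6L,
                                  tract_side_m = 1000,
                                  n_parks = 30L,
                                  park_area_mu_log = log(0.05),
                                  park_area_sigma_log = 1,
                                  park_placement = c("even", "clustered"),
                                  n_agents = 2000L,
                                  mean_other_activities = 1,
                                  displacement_scale_km = 2,
                                  segregation_alpha = 0.5,
                                  population_per_tract = 4000L,
                                  global_mix = c(White = 0.55, Black = 0.12,
                                                 Asian = 0.08, Hispanic = 0.20,
                                                 Other = 0.05),
                                  seed = 1L) {
  park_placement <- match.arg(park_placement)
  stopifnot(grid_rows > 0L, grid_cols > 0L, tract_side_m > 0, n_parks > 0L,
            n_agents > 0L, mean_other_activities >= 0,
            displacement_scale_km > 0, segregation_alpha > 0,
            population_per_tract > 0L,
            setequal(names(global_mix), group_order()),
            abs(sum(global_mix) - 1) < 1e-9)
  structure(as.list(environment()), class = "synthetic_city_config")
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Generate synthetic tracts and parks
#'
#' Tracts form a regular grid of squares; each tract's group counts are a
#' multinomial draw from a Dirichlet mixture concentrated around the global
#' mixture (`segregation_alpha * global_mix`). Parks are squares or discs
#' with log-normal areas, placed uniformly (`"even"`) or around three
#' Gaussian cluster centers (`"clustered"`).
#'
#' @param config a [synthetic_city_config()].
#' @return list with elements `tracts` and `parks`.
#' @export
generate_city <- function(config) {
  stopifnot(inherits(config, "synthetic_city_config"))
  .with_seed(config$seed, {
    side <- config$tract_side_m
    mix <- config$global_mix[group_order()]
    tracts <- list()
    k <- 0L
    # Dirichlet mixing over the four named groups only; the residual Other
    # share stays at its (small) global value so no tract ends up
    # Other-predominant, matching the expected data shape.
    named <- setdiff(group_order(), "Other")
    p_other <- mix["Other"]
    for (r in seq_len(config$grid_rows)) {
      for (cc in seq_len(config$grid_cols)) {
        k <- k + 1L
        p4 <- .rdirichlet1(config$segregation_alpha * mix[named] / sum(mix[named]))
        p <- stats::setNames(c(p4 * (1 - p_other), p_other), group_order())
        counts <- stats::rmultinom(1L, config$population_per_tract, p)[, 1L]
        tracts[[k]] <- tract(sprintf("t%03d", k),
                             rect_region((cc - 1L) * side, (r - 1L) * side,
                                         cc * side, r * side),
                             stats::setNames(counts, group_order()))
      }
    }
    W <- config$grid_cols * side; H <- config$grid_rows * side
    if (config$park_placement == "even") {
      cx <- stats::runif(config$n_parks, 0, W)
      cy <- stats::runif(config$n_parks, 0, H)
    } else {
      ctr <- cbind(stats::runif(3L, 0.15 * W, 0.85 * W),
                   stats::runif(3L, 0.15 * H, 0.85 * H))
      which_c <- sample.int(3L, config$n_parks, replace = TRUE)
      cx <- stats::rnorm(config$n_parks, ctr[which_c, 1L], 0.06 * W)
      cy <- stats::rnorm(config$n_parks, ctr[which_c, 2L], 0.06 * H)
    }
    areas_km2 <- stats::rlnorm(config$n_parks, config$park_area_mu_log,
                               config$park_area_sigma_log)
    parks <- vector("list", config$n_parks)
    for (j in seq_len(config$n_parks)) {
      a_m2 <- areas_km2[j] * 1e6
      if (j %% 2L == 1L) {
        h <- sqrt(a_m2) / 2
        reg <- rect_region(cx[j] - h, cy[j] - h, cx[j] + h, cy[j] + h)
      } else {
        # disc approximated by a 24-gon of the same area
        n <- 24L
        r_eff <- sqrt(a_m2 / (n / 2 * sin(2 * pi / n)))
        reg <- disc_region(cx[j], cy[j], r_eff, n = n)
      }
      parks[[j]] <- park(sprintf("p%03d", j), reg)
    }
    list(tracts = tracts, parks = parks)
  })
}

#' Generate synthetic daily trajectories
#'
#' Homes are uniform within tracts, tracts drawn proportionally to
#' population. Each agent gets `Poisson(mean_other_activities)` other-type
#' activities at isotropic displacements with exponential radial tail from
#' home, snapped to a 400 m grid and jittered uniformly within +-200 m
#' (mirroring the ~400 m spatial granularity of the mobility model).
#'
#' @param config a [synthetic_city_config()].
#' @param tracts tracts from [generate_city()].
#' @return a [trajectory_set()].
#' @export
generate_trajectories <- function(config, tracts) {
  stopifnot(inherits(config, "synthetic_city_config"))
  .with_seed(config$seed + 1L, {
    pop <- vapply(tracts, function(t) sum(t$group_counts), 0)
    idx <- sample.int(length(tracts), config$n_agents, replace = TRUE,
                      prob = pop)
    bbs <- lapply(tracts, function(t) .region_bbox(t$region))
    hx <- numeric(config$n_agents); hy <- numeric(config$n_agents)
    for (a in seq_len(config$n_agents)) {
      b <- bbs[[idx[a]]]
      hx[a] <- stats::runif(1L, b["xmin"], b["xmax"])
      hy[a] <- stats::runif(1L, b["ymin"], b["ymax"])
    }
    n_o <- stats::rpois(config$n_agents, config$mean_other_activities)
    agent <- sprintf("a%05d", seq_len(config$n_agents))
    oa_agent <- rep(agent, n_o)
    tot <- sum(n_o)
    rr <- stats::rexp(tot, rate = 1 / (config$displacement_scale_km * 1000))
    th <- stats::runif(tot, 0, 2 * pi)
    ox <- rep(hx, n_o) + rr * cos(th)
    oy <- rep(hy, n_o) + rr * sin(th)
    ox <- round(ox / 400) * 400 + stats::runif(tot, -200, 200)
    oy <- round(oy / 400) * 400 + stats::runif(tot, -200, 200)
    slot <- unlist(lapply(n_o, function(k) if (k > 0L) seq_len(k) else integer(0)))
    df <- rbind(
      data.frame(agent_id = agent, kind = rep("home", length(agent)),
                 x = hx, y = hy, slot = rep(NA_integer_, length(agent)),
                 stringsAsFactors = FALSE),
      data.frame(agent_id = oa_agent, kind = rep("other", tot),
                 x = ox, y = oy, slot = slot, stringsAsFactors = FALSE)
    )
    df <- df[order(df$agent_id, df$kind, df$slot), , drop = FALSE]
    rownames(df) <- NULL
    trajectory_set(df)
  })
}

#' Worked network-construction fixture
#'
#' One square tract (3 x 3 km), three small parks and two trajectories laid
#' out so that, at the 200 m exposure radius, the first trajectory's second
#' other-activity is exposed only to park p1; the second trajectory's second
#' other-activity is exposed to p1, p2 and p3, its fourth only to p3, and its
#' first and third share one unexposed location. The resulting incidence
#' matrix is `[2, 1, 2]`. All coordinates keep >= 50 m margins around the
#' 200 m threshold.
#'
#' @return list with `tracts`, `parks` and `trajectories`.
#' @export
worked_example_fixture <- function() {
  tracts <- list(tract("t1", rect_region(0, 0, 3000, 3000),
                       c(White = 600, Black = 150, Asian = 100,
                         Hispanic = 120, Other = 30)))
  parks <- list(
    park("p1", rect_region(750, 1500, 950, 1700)),
    park("p2", rect_region(1250, 1500, 1450, 1700)),
    park("p3", rect_region(1000, 1250, 1200, 1450))
  )
  traj <- data.frame(
    agent_id = c("u1", "u1", "u1", "u2", "u2", "u2", "u2", "u2"),
    kind = c("home", "other", "other", "home", "other", "other", "other", "other"),
    x = c(400, 300, 600, 2600, 2400, 1100, 2400, 1100),
    y = c(2600, 500, 1600, 2600, 600, 1600, 600, 1150),
    slot = c(NA, 1L, 2L, NA, 1L, 2L, 3L, 4L),
    stringsAsFactors = FALSE
  )
  list(tracts = tracts, parks = parks, trajectories = trajectory_set(traj))
}

#' Planted block-structured incidence matrix
#'
#' Test harness for modularity: entries are Poisson(within_weight) inside the
#' k diagonal tract-park blocks and Poisson(between_weight) elsewhere;
#' `between_weight = 0` yields disconnected blocks.
#'
#' @param k_blocks number of blocks.
#' @param tracts_per_block,parks_per_block block sizes.
#' @param within_weight,between_weight Poisson means.
#' @param seed RNG seed.
#' @return an [exposure_network()] with attribute `block` (list of tract and
#'   park block assignments).
#' @export
planted_partition_incidence <- function(k_blocks, tracts_per_block,
                                        parks_per_block, within_weight,
                                        between_weight = 0, seed = 1L) {
  stopifnot(k_blocks >= 1L, tracts_per_block >= 1L, parks_per_block >= 1L,
            within_weight >= 0, between_weight >= 0)
  nT <- k_blocks * tracts_per_block
  nP <- k_blocks * parks_per_block
  bT <- rep(seq_len(k_blocks), each = tracts_per_block)
  bP <- rep(seq_len(k_blocks), each = parks_per_block)
  X <- .with_seed(seed, {
    lam <- ifelse(outer(bT, bP, "=="), within_weight, between_weight)
    matrix(stats::rpois(nT * nP, lam), nT, nP)
  })
  net <- exposure_network(X, sprintf("t%03d", seq_len(nT)),
                          sprintf("p%03d", seq_len(nP)))
  attr(net, "block") <- list(tract = bT, park = bP)
  net
}
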