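# Log-binned densities, log-normal fits, visited-park areas, travel distance.

test_that("log-binned histogram uses geometric left-closed bins", {
  # left-closed right-open decade bins [1,10), [10,100), [100,1000]:
  # 1 -> bin 1, 10 -> bin 2, 100 and 1000 -> bin 3
  lb <- log_binned_density(c(1, 10, 100, 1000), n_bins = 3L)
  expect_equal(lb$counts, c(1, 1, 2))
  expect_equal(lb$bin_edges, 10^(0:3), tolerance = 1e-12)
  # integral of density over bin widths = fraction of values included
  expect_equal(sum(lb$density * diff(lb$bin_edges)), 1)
  lb2 <- log_binned_density(c(0, 0, 1, 10, 100, 1000), n_bins = 3L)
  expect_identical(lb2$n_zero_excluded, 2L)
  expect_equal(sum(lb2$density * diff(lb2$bin_edges)), 4 / 6)
  # all equal: single occupied bin, integral 1
  lb3 <- log_binned_density(rep(7, 5), n_bins = 4L)
  expect_equal(sum(lb3$counts), 5)
  expect_equal(sum(lb3$density * diff(lb3$bin_edges)), 1)
  # integral ~ 1 on random log-normal samples
  set.seed(3)
  lb4 <- log_binned_density(rlnorm(5000, 2, 1), n_bins = 25L)
  expect_equal(sum(lb4$density * diff(lb4$bin_edges)), 1, tolerance = 1e-9)
})

test_that("log-normal fit recovers parameters and respects scaling", {
  set.seed(19)
  v <- rlnorm(20000, meanlog = 6, sdlog = 1)
  f <- fit_lognormal(v)
  expect_lt(abs(f$mu_log - 6) / 6, 0.01)
  expect_lt(abs(f$sigma_log - 1), 0.02)
  expect_equal(f$mu_natural, exp(f$mu_log + f$sigma_log^2 / 2))
  expect_equal(f$sigma_natural,
               f$mu_natural * sqrt(exp(f$sigma_log^2) - 1))
  # scaling by k shifts mu_log by log k, leaves sigma_log unchanged
  f2 <- fit_lognormal(3.5 * v)
  expect_equal(f2$mu_log, f$mu_log + log(3.5), tolerance = 1e-12)
  expect_equal(f2$sigma_log, f$sigma_log, tolerance = 1e-12)
  expect_error(fit_lognormal(rep(2, 10)), "degenerate")
  expect_error(fit_lognormal(c(1, 2, -1)), "positive")
})

test_that("mean visited-park area is the visit-weighted neighbor average", {
  parks <- list(park("p1", rect_region(0, 0, 1000, 1000)),       # 1 km^2
                park("p2", rect_region(2000, 0, 2000 + sqrt(2) * 1000, 1000 * sqrt(2))),
                park("p3", rect_region(5000, 0, 7000, 2000)))    # 4 km^2
  net <- exposure_network(matrix(c(2, 1, 2), 1, 3), "t1",
                          c("p1", "p2", "p3"))
  got <- mean_visited_park_area(net, parks)
  expect_equal(unname(got), (2 * 1 + 1 * 2 + 2 * 4) / 5, tolerance = 1e-9)
  # single park: every connected tract gets its area
  net1 <- exposure_network(matrix(c(3, 5), 2, 1), c("t1", "t2"), "p1")
  one <- list(park("p1", rect_region(0, 0, 500, 500)))
  expect_equal(unname(mean_visited_park_area(net1, one)), c(0.25, 0.25))
  # always within [min, max] park area
  set.seed(37)
  X <- matrix(rpois(12, 1), 3, 4)
  areas <- runif(4, 0.1, 9)
  netr <- exposure_network(X, paste0("t", 1:3), paste0("p", 1:4))
  parksr <- lapply(1:4, function(j) {
    s <- sqrt(areas[j] * 1e6)
    park(paste0("p", j), rect_region(j * 10000, 0, j * 10000 + s, s))
  })
  got <- mean_visited_park_area(netr, parksr)
  ok <- !is.na(got)
  expect_true(all(got[ok] >= min(areas) - 1e-9 & got[ok] <= max(areas) + 1e-9))
})

test_that("median travel distance aggregates per trajectory then per tract", {
  tracts <- list(tract("t1", rect_region(-100, -100, 6000, 6000), c(White = 10)))
  traj <- trajectory_set(data.frame(
    agent_id = c("a", "a", "a", "a", "b"),
    kind = c("home", "other", "other", "other", "home"),
    x = c(0, 3000, 0, 0, 10),
    y = c(0, 0, 4000, 5000, 10)))
  d <- median_home_other_distance(traj, tracts)
  expect_equal(unname(d["t1"]), 4)  # median of 3, 4, 5 km
  expect_identical(attr(d, "n_excluded_no_other"), 1L)  # agent b
  # rigid translation leaves distances unchanged
  tr2 <- as.data.frame(traj)
  tr2$x <- tr2$x + 5e5; tr2$y <- tr2$y - 7e5
  tracts2 <- list(tract("t1", rect_region(-100 + 5e5, -100 - 7e5,
                                          6000 + 5e5, 6000 - 7e5), c(White = 10)))
  d2 <- median_home_other_distance(trajectory_set(tr2), tracts2)
  expect_equal(unname(d2["t1"]), unname(d["t1"]), tolerance = 1e-9)
  # brute-force per-pair check on a synthetic city
  cfg <- synthetic_city_config(grid_rows = 2L, grid_cols = 2L, n_parks = 2L,
                               n_agents = 40L, mean_other_activities = 2,
                               seed = 77L)
  city <- generate_city(cfg)
  tj <- generate_trajectories(cfg, city$tracts)
  got <- median_home_other_distance(tj, city$tracts)
  df <- as.data.frame(tj)
  homes <- df[df$kind == "home", ]
  med <- sapply(split(seq_len(nrow(df))[df$kind == "other"],
                      df$agent_id[df$kind == "other"]), function(idx) {
    a <- df$agent_id[idx[1]]
    h <- homes[homes$agent_id == a, ]
    median(sqrt((df$x[idx] - h$x)^2 + (df$y[idx] - h$y)^2) / 1000)
  })
  ht <- assign_home_tract(cbind(homes$x, homes$y), city$tracts)
  names(ht) <- homes$agent_id
  for (tid in unique(stats::na.omit(ht[names(med)]))) {
    want <- median(med[names(med) %in% names(ht)[!is.na(ht) & ht == tid]])
    expect_equal(unname(got[tid]), want, tolerance = 1e-12)
  }
})
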