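# Strengths, weighted neighbor averages, labeling, homophily, crosstabs.

mk_net <- function(X) {
  exposure_network(X, sprintf("t%02d", seq_len(nrow(X))),
                   sprintf("p%02d", seq_len(ncol(X))))
}

test_that("strengths are row/column sums", {
  net <- mk_net(matrix(c(2, 1, 2), 1, 3))
  expect_equal(unname(tract_strength(net)), 5)
  expect_equal(unname(park_strength(net)), c(2, 1, 2))
  net2 <- mk_net(diag(c(3, 4)))
  expect_equal(unname(park_strength(net2)), c(3, 4))
  set.seed(1)
  X <- matrix(rpois(35, 2), 5, 7)
  netr <- mk_net(X)
  expect_equal(unname(tract_strength(netr)), rowSums(X))
  expect_equal(unname(park_strength(netr)), colSums(X))
  expect_equal(sum(tract_strength(netr)), sum(park_strength(netr)))
})

test_that("neighbor_weighted_average evaluates the weighted mean exactly", {
  net <- mk_net(matrix(c(2, 1, 2), 1, 3))
  a <- 1.5; b <- -2; cc <- 7
  expect_equal(unname(neighbor_weighted_average(net, c(a, b, cc), "park")),
               (2 * a + b + 2 * cc) / 5)
  # constant attribute -> constant average on every connected node
  expect_equal(unname(neighbor_weighted_average(net, rep(3.3, 3), "park")), 3.3)
  # zero-strength nodes are flagged missing, never silently 0
  X <- rbind(c(1, 2), c(0, 0))
  net2 <- mk_net(X)
  out <- neighbor_weighted_average(net2, c(10, 20), "park")
  expect_true(is.na(out[2]))
  expect_equal(unname(out[1]), 50 / 3)
  # tract-side attribute onto parks
  outP <- neighbor_weighted_average(net2, c(2, 99), "tract")
  expect_equal(unname(outP), c(2, 2))
})

test_that("label_tracts takes the argmax with group-order tie-breaks", {
  t1 <- tract("a", rect_region(0, 0, 1, 1),
              c(White = 60, Black = 20, Asian = 10, Hispanic = 10))
  t2 <- tract("b", rect_region(2, 0, 3, 1),
              c(White = 30, Hispanic = 30, Black = 5))
  lab <- label_tracts(list(t1, t2))
  expect_identical(lab$label, c("White", "White"))
  expect_identical(lab$tie_flag, c(FALSE, TRUE))
  # random tables vs direct argmax
  set.seed(5)
  tr <- lapply(1:20, function(k) {
    tract(sprintf("t%02d", k), rect_region(k, 0, k + 1, 1),
          stats::setNames(rpois(5, 20), group_order()))
  })
  # random counts can make Other predominant; that path warns by design
  lab2 <- suppressWarnings(label_tracts(tr))
  want <- vapply(tr, function(t) {
    v <- t$group_counts[group_order()]
    group_order()[which.max(v)]  # which.max picks first max = group order
  }, "")
  expect_identical(lab2$label, want)
})

test_that("label_parks weights tract mixtures by visits", {
  # park 1 linked only to a pure-Hispanic tract; park 2 50/50 White/Black
  tr <- list(tract("t1", rect_region(0, 0, 1, 1), c(Hispanic = 100)),
             tract("t2", rect_region(2, 0, 3, 1), c(White = 100)),
             tract("t3", rect_region(4, 0, 5, 1), c(Black = 100)))
  X <- rbind(c(4, 0), c(0, 3), c(0, 3))
  net <- exposure_network(X, c("t1", "t2", "t3"), c("pa", "pb"))
  lab <- label_parks(net, tr)
  expect_identical(lab$label, c("Hispanic", "White"))
  expect_identical(lab$tie_flag, c(FALSE, TRUE))  # White wins the 50/50 tie
  # proportions over the five groups sum to 1 for connected parks
  expect_equal(unname(rowSums(lab[, group_order()])), c(1, 1), tolerance = 1e-9)
  # zero-strength park is unlabeled
  X2 <- cbind(X, 0)
  net2 <- exposure_network(X2, c("t1", "t2", "t3"), c("pa", "pb", "pc"))
  expect_true(is.na(label_parks(net2, tr)$label[3]))
})

test_that("homophily matches its defining sum and both sides count the same links", {
  net <- mk_net(matrix(c(2, 1, 2), 1, 3))
  h1 <- homophily(net, "White", c("White", "White", "White"))
  expect_equal(unname(h1$h_tract), 1)
  expect_equal(unname(h1$h_park), c(1, 1, 1))
  h0 <- homophily(net, "Hispanic", c("White", "White", "White"))
  expect_equal(unname(h0$h_tract), 0)
  set.seed(6)
  for (rep in 1:50) {
    nT <- sample(2:6, 1); nP <- sample(2:6, 1)
    netr <- rand_exposure_net(nT, nP)
    lT <- sample(c("White", "Black", "Asian"), nT, replace = TRUE)
    lP <- sample(c("White", "Black", "Asian"), nP, replace = TRUE)
    h <- homophily(netr, lT, lP)
    X <- as.matrix(netr$X)
    sT <- unname(rowSums(X)); sP <- unname(colSums(X))
    # direct-sum oracle
    for (i in seq_len(nT)) {
      if (sT[i] > 0) {
        expect_equal(unname(h$h_tract[i]), sum(X[i, lP == lT[i]]) / sT[i])
      } else {
        expect_true(is.na(h$h_tract[i]))
      }
    }
    # identity: total same-label weight counted from either side
    lhs <- sum(sT * h$h_tract, na.rm = TRUE)
    rhs <- sum(sP * h$h_park, na.rm = TRUE)
    expect_equal(lhs, rhs)
    expect_true(all(is.na(h$h_tract) | (h$h_tract >= 0 & h$h_tract <= 1)))
  }
})

test_that("group crosstabs match hand counts on a built layout", {
  # two tract regions: west White, east Hispanic; 5 parks by centroid
  tr <- list(tract("tw", rect_region(0, 0, 100, 100), c(White = 90, Hispanic = 10)),
             tract("te", rect_region(100, 0, 200, 100), c(Hispanic = 80, White = 20)))
  mkpark <- function(id, cx, cy) park(id, rect_region(cx - 5, cy - 5, cx + 5, cy + 5))
  parks <- list(mkpark("p1", 20, 50), mkpark("p2", 40, 50), mkpark("p3", 80, 50),
                mkpark("p4", 120, 50), mkpark("p5", 180, 50))
  t_lab <- label_tracts(tr)
  p_lab <- c("White", "White", "Hispanic", "Hispanic", "Hispanic")
  ct <- group_crosstabs(tr, parks, t_lab, p_lab)
  bg <- ct$by_group
  expect_equal(bg$n_tracts[bg$group == "White"], 1)
  expect_equal(bg$n_parks[bg$group == "Hispanic"], 3)
  expect_equal(bg$pct_city_area[bg$group == "White"], 50)
  pw <- ct$parks_within_tracts
  w <- pw[pw$tract_group == "White", ]
  expect_equal(w$total_parks, 3)                   # p1, p2, p3 centroids in tw
  expect_equal(w$pct_White, 100 * 2 / 3)
  expect_equal(w$pct_Hispanic, 100 / 3)
  h <- pw[pw$tract_group == "Hispanic", ]
  expect_equal(h$total_parks, 2)
  expect_equal(h$pct_Hispanic, 100)
  # every non-empty row sums to 100
  sums <- rowSums(pw[, paste0("pct_", setdiff(group_order(), "Other"))])
  expect_true(all(abs(sums[pw$total_parks > 0] - 100) < 0.01))
})

test_that("homophily_summary aggregates by group and side", {
  net <- mk_net(rbind(c(3, 0), c(1, 1)))
  hs <- homophily_summary(homophily(net, c("White", "Black"), c("White", "Black")),
                          c("White", "Black"), c("White", "Black"))
  expect_equal(hs$mean[hs$group == "White" & hs$side == "tract"], 1)
  expect_equal(hs$mean[hs$group == "Black" & hs$side == "tract"], 0.5)
  expect_equal(hs$n[hs$group == "Hispanic" & hs$side == "park"], 0)
})
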