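# Tag filtering, park merging, home-tract assignment, park-area fraction.

sq <- function(x0, y0, s) rect_region(x0, y0, x0 + s, y0 + s)

test_that("filter_osm_parks keeps exactly the listed tag/value pairs", {
  mk <- function(id, tags, geom = TRUE) {
    list(id = id, tags = tags,
         region = if (geom) sq(0, 0, 10) else NULL)
  }
  records <- list(
    mk("r1", c(leisure = "park")),
    mk("r2", c(leisure = "pitch")),          # not in the listed set
    mk("r3", c(landuse = "nature_reserve")),
    mk("r4", c(natural = "beach")),
    mk("r5", c(boundary = "protected_area", name = "x")),
    mk("r6", c(landuse = "residential")),
    mk("r7", c(natural = "water")),
    mk("r8", c(leisure = "golf_course")),
    mk("r9", character(0)),
    mk("r10", c(leisure = "dog_park"))
  )
  out <- filter_osm_parks(records)
  expect_identical(sort(vapply(out, function(p) p$park_id, "")),
                   c("r1", "r10", "r3", "r4", "r5", "r8"))
  # matching record without geometry is dropped with a warning
  expect_warning(out2 <- filter_osm_parks(list(mk("g1", c(leisure = "park"), geom = FALSE),
                                               mk("g2", c(leisure = "park")))),
                 "lack geometry")
  expect_length(out2, 1L)
  expect_identical(attr(out2, "n_no_geometry"), 1L)
})

test_that("merging handles containment, disjoint sets and chains", {
  # B strictly inside A -> only the bigger polygon's region/area remains
  m1 <- merge_overlapping_parks(list(park("A", sq(0, 0, 10)),
                                     park("B", sq(2, 2, 2))))
  expect_length(m1, 1L)
  expect_equal(m1[[1]]$area_km2 * 1e6, 100)
  expect_identical(m1[[1]]$absorbed_ids, c("A", "B"))
  expect_identical(m1[[1]]$park_id, "A")

  # two disjoint squares stay two parks
  m2 <- merge_overlapping_parks(list(park("A", sq(0, 0, 1)),
                                     park("B", sq(5, 5, 1))))
  expect_length(m2, 2L)

  # chain A-B overlap, B-C overlap, A-C disjoint -> one park, union area
  A <- park("A", rect_region(0, 0, 4, 4))
  B <- park("B", rect_region(3, 0, 7, 4))
  C <- park("C", rect_region(6, 0, 10, 4))
  m3 <- merge_overlapping_parks(list(A, B, C))
  expect_length(m3, 1L)
  expect_equal(m3[[1]]$area_km2 * 1e6, 40, tolerance = 1e-9)
  # boundary-touching squares do NOT merge (interior-disjoint already)
  m4 <- merge_overlapping_parks(list(park("A", sq(0, 0, 2)),
                                     park("B", sq(2, 0, 2))))
  expect_length(m4, 2L)
})

test_that("merging is idempotent and conserves total union area", {
  set.seed(41)
  for (rep in 1:3) {
    parks <- lapply(1:12, function(k) {
      park(sprintf("p%02d", k),
           rand_poly_region(runif(1, 0, 60), runif(1, 0, 60), 4, 14))
    })
    merged <- merge_overlapping_parks(parks)
    # conservation: union of outputs equals union of inputs
    a_in <- region_union_area(lapply(parks, function(p) p$region))
    a_out <- sum(vapply(merged, function(p) p$area_km2 * 1e6, 0))
    expect_lt(abs(a_out - a_in) / a_in, 1e-6)
    # outputs pairwise interior-disjoint
    if (length(merged) > 1L) {
      for (i in 1:(length(merged) - 1L)) for (j in (i + 1L):length(merged)) {
        inter <- region_intersection_area(merged[[i]]$region, merged[[j]]$region)
        expect_lt(inter, 1e-6)
      }
    }
    # idempotent: merging again is a no-op
    again <- merge_overlapping_parks(merged)
    expect_equal(length(again), length(merged))
    expect_identical(lapply(again, function(p) p$absorbed_ids),
                     lapply(merged, function(p) p$absorbed_ids))
    expect_equal(vapply(again, function(p) p$area_km2, 0),
                 vapply(merged, function(p) p$area_km2, 0), tolerance = 1e-12)
  }
})

test_that("assign_home_tract matches brute-force containment", {
  tracts <- list(tract("t1", sq(0, 0, 10), c(White = 1)),
                 tract("t2", sq(10, 0, 10), c(White = 1)),
                 tract("t3", sq(0, 10, 10), c(White = 1)))
  expect_identical(as.character(assign_home_tract(c(5, 5), tracts)), "t1")
  expect_true(is.na(assign_home_tract(c(50, 50), tracts)))
  set.seed(51)
  pts <- cbind(runif(100, -2, 25), runif(100, -2, 25))
  got <- assign_home_tract(pts, tracts)
  tids <- c("t1", "t2", "t3")
  want <- vapply(seq_len(nrow(pts)), function(k) {
    hit <- which(vapply(tracts, function(t) {
      oracle_region_contains(pts[k, 1], pts[k, 2], t$region)
    }, TRUE))
    if (length(hit)) tids[min(hit)] else NA_character_
  }, "")
  # away from boundaries the assignments must agree exactly
  on_boundary <- vapply(seq_len(nrow(pts)), function(k) {
    any(vapply(tracts, function(t) {
      oracle_region_distance(pts[k, 1], pts[k, 2], t$region) < 1e-9 &&
        !oracle_region_contains(pts[k, 1], pts[k, 2], t$region)
    }, TRUE))
  }, TRUE)
  expect_identical(as.character(got)[!on_boundary], want[!on_boundary])
})

test_that("shared-boundary points go to the lexicographically smallest tract id", {
  tracts <- list(tract("tb", sq(0, 0, 10), c(White = 1)),
                 tract("ta", sq(10, 0, 10), c(White = 1)))
  # x = 10 lies on the shared edge; must deterministically resolve to "ta"
  got <- assign_home_tract(rbind(c(10, 5)), tracts)
  expect_identical(as.character(got), "ta")
})

test_that("park_area_fraction matches analytic intersections and is coherent", {
  tracts <- list(tract("t1", rect_region(0, 0, 1000, 1000), c(White = 1)),
                 tract("t2", rect_region(1000, 0, 2000, 1000), c(White = 1)))
  expect_equal(unname(park_area_fraction(tracts, list())), c(0, 0))
  # park covering the left half of t1 (and spilling outside the tract)
  p_half <- list(park("p", rect_region(-200, -200, 500, 1200)))
  expect_equal(unname(park_area_fraction(tracts, p_half)), c(0.5, 0))
  # tract fully covered
  p_all <- list(park("p", rect_region(-10, -10, 1010, 1010)))
  expect_equal(unname(park_area_fraction(tracts, p_all))[1], 1)
  # area-weighted fractions sum to area(parks intersect union of tracts)
  set.seed(61)
  parks <- lapply(1:6, function(k) {
    park(sprintf("p%d", k), rand_poly_region(runif(1, 0, 2000), runif(1, 0, 1000), 50, 260))
  })
  parks <- merge_overlapping_parks(parks)
  fr <- park_area_fraction(tracts, parks)
  lhs <- sum(fr * c(1e6, 1e6))
  rhs <- sum(vapply(tracts, function(t) {
    sum(vapply(parks, function(p) region_intersection_area(p$region, t$region), 0))
  }, 0))
  expect_equal(lhs, rhs, tolerance = 1e-6)
  expect_true(all(fr >= 0 & fr <= 1))
})
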