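collinear3 <- data.frame(id = c("p1", "p2", "p3"),
                         x = c(0, 100, 200), y = 0,
                         a_index = c(1, 2, 3))

test_that("distance-band neighbor sets match the geometry", {
  nbr <- distance_band_neighbors(collinear3, band = 150)
  expect_equal(lengths(nbr), c(2L, 3L, 2L))
  expect_equal(sort(nbr[[2]]), 1:3)

  # band below the minimum spacing: every point self-neighbored only
  tight <- distance_band_neighbors(collinear3, band = 50)
  expect_equal(lengths(tight), c(1L, 1L, 1L))
  expect_equal(unlist(tight), 1:3)

  no_self <- distance_band_neighbors(collinear3, band = 150,
                                     include_self = FALSE)
  expect_equal(lengths(no_self), c(1L, 2L, 1L))
})

test_that("default band is the largest nearest-neighbor distance", {
  pts <- data.frame(x = c(0, 100, 350), y = 0)
  nbr <- distance_band_neighbors(pts)
  expect_equal(attr(nbr, "band"), 250)  # point 3's nearest neighbor
  expect_true(all(lengths(nbr) >= 2))   # nobody isolated at that band
  expect_error(distance_band_neighbors(pts[1, , drop = FALSE]),
               class = "e2sfca_error_too_few_points")
})

test_that("neighbor sets equal the exhaustive pairwise scan", {
  withr::local_seed(7)
  pts <- data.frame(x = runif(100, 0, 1000), y = runif(100, 0, 1000))
  nbr <- distance_band_neighbors(pts, band = 120)
  for (i in seq_len(nrow(pts))) {
    d <- sqrt((pts$x - pts$x[i])^2 + (pts$y - pts$y[i])^2)
    expect_equal(sort(nbr[[i]]), which(d <= 120))
  }
})

test_that("hand-computed three-point Gi* z-scores are exact", {
  nbr <- distance_band_neighbors(collinear3, band = 150)
  z <- gi_star(collinear3$a_index, nbr)$gi_z
  expect_equal(z, c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  expect_equal(z[2], 0)  # middle numerator is exactly zero
})

test_that("identical values give z = 0 everywhere", {
  nbr <- distance_band_neighbors(collinear3, band = 150)
  expect_equal(gi_star(rep(5, 3), nbr)$gi_z, c(0, 0, 0))
})

test_that("Gi* matches the direct-formula oracle on random instances", {
  for (seed in 1:3) {
    withr::local_seed(seed)
    pts <- data.frame(x = runif(50, 0, 800), y = runif(50, 0, 800))
    vals <- rgamma(50, 2, 1)
    nbr <- distance_band_neighbors(pts, band = 200)
    got <- gi_star(vals, nbr)$gi_z
    want <- oracle_gi(vals, pts$x, pts$y, 200)
    expect_lt(max(abs(got - want)), 1e-9)
  }
})

test_that("z-scores are invariant to location and scale of the values", {
  withr::local_seed(11)
  pts <- data.frame(x = runif(60, 0, 500), y = runif(60, 0, 500))
  vals <- rnorm(60, 10, 3)
  nbr <- distance_band_neighbors(pts, band = 150)
  z0 <- gi_star(vals, nbr)$gi_z
  expect_lt(max(abs(gi_star(vals + 100, nbr)$gi_z - z0)), 1e-9)
  expect_lt(max(abs(gi_star(vals * 7.5, nbr)$gi_z - z0)), 1e-9)
  expect_lt(max(abs(gi_star(vals * 3 - 40, nbr)$gi_z - z0)), 1e-9)
})

test_that("numerators sum to zero when weights are symmetric with equal W_i", {
  withr::local_seed(29)
  # complete graph: band beyond the lattice diameter, W_i = n for all i
  grid <- expand.grid(x = seq(0, 400, by = 100), y = seq(0, 400, by = 100))
  nbr <- distance_band_neighbors(grid, band = 1e6)
  vals <- rnorm(nrow(grid))
  wi <- lengths(nbr)
  expect_true(all(wi == nrow(grid)))
  nums <- vapply(seq_along(nbr),
                 function(i) sum(vals[nbr[[i]]]) - mean(vals) * wi[i],
                 double(1))
  expect_lt(abs(sum(nums)), 1e-9)
  # local band with equal W_i: the four corners of a square at a band
  # equal to the side length (self + 2 adjacent corners each)
  sq <- data.frame(x = c(0, 100, 100, 0), y = c(0, 0, 100, 100))
  nbr2 <- distance_band_neighbors(sq, band = 100)
  vals2 <- rnorm(4)
  wi2 <- lengths(nbr2)
  expect_true(all(wi2 == 3))
  nums2 <- vapply(seq_along(nbr2),
                  function(i) sum(vals2[nbr2[[i]]]) - mean(vals2) * wi2[i],
                  double(1))
  expect_lt(abs(sum(nums2)) / max(abs(nums2)), 1e-9)
})

test_that("z-scores are invariant under rigid motions of the points", {
  withr::local_seed(13)
  pts <- data.frame(id = sprintf("p%d", 1:40),
                    x = runif(40, 0, 600), y = runif(40, 0, 600),
                    a_index = rexp(40))
  hs <- hotspot(pts, band = 250)
  moved <- rigid_transform(pts, -1.2, 5000, 300)
  hs2 <- hotspot(moved, band = 250)
  expect_lt(max(abs(hs$table$gi_z - hs2$table$gi_z)), 1e-9)
})

test_that("mismatched value vectors are rejected", {
  nbr <- distance_band_neighbors(collinear3, band = 150)
  expect_error(gi_star(1:2, nbr), class = "e2sfca_error_length_mismatch")
})

test_that("confidence bins follow the two-tailed z thresholds", {
  z <- c(-3, -2.58, -2.0, -1.7, -1.0, 0, 1.0, 1.645, 1.7, 2.0, 2.58, 3)
  bins <- classify_bins(z)$gi_bin
  expect_equal(bins, c(-3L, -3L, -2L, -1L, 0L, 0L, 0L, 1L, 1L, 2L, 3L, 3L))
  expect_equal(classify_bins(2.0)$gi_p, 2 * pnorm(-2), tolerance = 1e-12)
})

test_that("FDR binning uses Benjamini-Hochberg adjusted p-values", {
  # one strong value among many mild ones: BH keeps the strong one but
  # can demote the mild ones relative to raw-z binning
  z <- c(4, rep(1.7, 9))
  raw <- classify_bins(z, fdr = FALSE)$gi_bin
  adj <- classify_bins(z, fdr = TRUE)
  expect_equal(raw[2:10], rep(1L, 9))
  expect_equal(adj$gi_q, p.adjust(2 * pnorm(-abs(z)), "BH"))
  expect_equal(adj$gi_bin[1], 3L)
  # mild points: raw p ~0.089, BH-adjusted ~0.099 -> still 90% but any
  # tightening to 95% must fail
  expect_true(all(adj$gi_bin[2:10] <= 1L))
  expect_true(all(adj$gi_bin[adj$gi_q > 0.10] == 0L))
})

test_that("per-area summaries tally every point exactly once", {
  withr::local_seed(17)
  pts <- data.frame(id = sprintf("p%d", 1:80),
                    x = runif(80, 0, 2000), y = runif(80, 0, 2000),
                    a_index = rexp(80),
                    area_label = sample(c("north", "south"), 80, TRUE))
  hs <- hotspot(pts, band = 500)
  summ <- hotspot_summary(hs)
  expect_equal(sum(summ$n), 80)
  tally <- table(hs$table$area_label, hs$table$gi_bin)
  for (r in seq_len(nrow(summ))) {
    expect_equal(summ$n[r],
                 unname(tally[summ$area_label[r],
                              as.character(summ$gi_bin[r])]))
  }
  # all-zero bins collapse to a single nonsignificant class per area
  flat <- hs$table
  flat$gi_bin <- 0L
  s2 <- hotspot_summary(flat)
  expect_true(all(s2$class == "not_significant"))
  expect_equal(sum(s2$n), 80)
})
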