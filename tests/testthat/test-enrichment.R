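# The enrichment ratio: exact values on constructed regions, brute-force
# agreement, bounds, and dataset-level scoring behaviour.

test_that("uniform green and max-containing loci give ratio exactly 1", {
  nuc <- make_nucleus(disc_mask(c(32L, 32L), c(16, 16), 10))
  loc <- make_locus(disc_mask(c(32L, 32L), c(18, 18), 2) & nuc$mask)
  flat <- matrix(5, 32, 32)
  expect_identical(enrichment_ratio(flat, loc, nuc)$value, 1)

  g <- matrix(runif(32 * 32), 32)
  peak <- which(nuc$mask & g == max(g[nuc$mask]), arr.ind = TRUE)
  g[peak] <- 2  # unambiguous global max
  loc2 <- make_locus(disc_mask(c(32L, 32L), peak[1, ], 2) & nuc$mask)
  expect_identical(enrichment_ratio(g, loc2, nuc)$value, 1)
})

test_that("a 5x5 toy nucleus matches the enumerated voxel-scan oracle", {
  green <- matrix(c(
    3, 8, 1, 4, 2,
    7, 2, 9, 5, 6,
    1, 5, 4, 12, 3,
    2, 6, 11, 7, 1,
    4, 3, 2, 6, 5), 5, byrow = TRUE)
  nuc <- make_nucleus(matrix(TRUE, 5, 5))
  locus_mask <- matrix(FALSE, 5, 5)
  locus_mask[3:4, 3:4] <- TRUE
  loc <- make_locus(locus_mask)
  r <- enrichment_ratio(green, loc, nuc)
  expect_identical(r$value, brute_force_ratio(green, locus_mask, nuc$mask))
  expect_identical(r$value, 1)        # the 12 sits inside the locus block
  expect_identical(r$locus_max, 12)
  expect_identical(r$nucleus_max, 12)
})

test_that("strict max agrees exactly with brute force on random toys", {
  set.seed(99)
  for (i in 1:25) {
    d <- sample(8:32, 2)
    nuc_mask <- disc_mask(d, d / 2, min(d) / 2 - 1)
    g <- array(rpois(prod(d), 50) * 1.0, dim = d)
    pts <- which(nuc_mask)
    locus_mask <- array(FALSE, dim = d)
    locus_mask[sample(pts, max(1, length(pts) %/% 10))] <- TRUE
    v <- enrichment_ratio(g, make_locus(locus_mask),
                          make_nucleus(nuc_mask))$value
    expect_identical(v, brute_force_ratio(g, locus_mask, nuc_mask))
    expect_true(v > 0 && v <= 1)
  }
})

test_that("adding a constant background pushes the ratio towards 1", {
  nuc <- make_nucleus(disc_mask(c(24L, 24L), c(12, 12), 9))
  loc <- make_locus(disc_mask(c(24L, 24L), c(15, 12), 2) & nuc$mask)
  set.seed(4)
  g <- matrix(runif(24 * 24, 1, 10), 24)
  vals <- vapply(c(0, 5, 20, 100),
                 function(c0) enrichment_ratio(g + c0, loc, nuc)$value, 0)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals <= 1))
})

test_that("the quantile estimator is less noise-sensitive than the max", {
  sc <- generate_scene(small_spec(seed = 8, enrichment_beta = 0))
  nuc <- segment_nucleus(sc$stack$channels$dapi, min_size = 200)
  roi <- suppressWarnings(detect_locus(sc$stack$channels$red, nuc))
  smax <- enrichment_ratio(sc$stack$channels$green, roi, nuc)
  sq <- enrichment_ratio(sc$stack$channels$green, roi, nuc,
                         estimator = "quantile", q = 0.9)
  expect_match(sq$estimator, "quantile")
  expect_true(sq$value > 0 && sq$value <= 1)
  expect_false(identical(smax$value, sq$value))
})

test_that("degenerate and invalid regions raise classed errors", {
  nuc <- make_nucleus(disc_mask(c(16L, 16L), c(8, 8), 5))
  loc <- make_locus(disc_mask(c(16L, 16L), c(9, 9), 1) & nuc$mask)
  expect_error(enrichment_ratio(matrix(0, 16, 16), loc, nuc),
               class = "degenerateSignal")
  outside <- make_locus(disc_mask(c(16L, 16L), c(2, 2), 1))
  expect_error(enrichment_ratio(matrix(1, 16, 16), outside, nuc),
               class = "invalidRegions")
  empty <- make_locus(matrix(FALSE, 16, 16))
  expect_error(enrichment_ratio(matrix(1, 16, 16), empty, nuc),
               class = "emptyLocus")
})

test_that("scoring a dataset is deterministic and respects bounds", {
  base <- scene_spec(shape = c(96L, 96L), locus_sigma = 2)
  ds <- generate_condition_dataset("SCR_EXD_WT", 5, 2, seed = 13,
                                   base_spec = base)
  s1 <- score_dataset(ds, min_nucleus_size = 200)
  s2 <- score_dataset(ds, min_nucleus_size = 200)
  expect_identical(s1, s2)
  expect_true(all(s1$scores$value > 0 & s1$scores$value <= 1))
  expect_identical(nrow(s1$scores) + nrow(s1$exclusions), 10L)

  empty <- score_dataset(ds$manifest[0, ])
  expect_identical(nrow(empty$scores), 0L)
  expect_identical(nrow(empty$exclusions), 0L)
})

test_that("mean score increases with the enrichment effect size", {
  score_at <- function(beta, seeds) {
    vapply(seeds, function(s) {
      sc <- generate_scene(small_spec(seed = s, enrichment_beta = beta))
      nuc <- segment_nucleus(sc$stack$channels$dapi, min_size = 200)
      roi <- suppressWarnings(detect_locus(sc$stack$channels$red, nuc))
      enrichment_ratio(sc$stack$channels$green, roi, nuc)$value
    }, 0)
  }
  seeds <- 1:40
  m0 <- mean(score_at(0, seeds))
  m05 <- mean(score_at(0.5, seeds))
  m15 <- mean(score_at(1.5, seeds))
  expect_gt(m05, m0)
  # at strong effects the bounded ratio saturates near 1: non-decreasing
  expect_gte(m15, m05 - 0.01)
  expect_gt(m15, 0.95)
})

test_that("unreadable files are recorded as exclusions, not failures", {
  base <- scene_spec(shape = c(96L, 96L), locus_sigma = 2)
  ds <- generate_condition_dataset("SCR_EXD_WT", 2, 1, seed = 3,
                                   base_spec = base)
  m <- ds$manifest
  m$path <- file.path(tempdir(), c("missing_a.tif", "missing_b.tif"))
  m$scene_id <- c("x1", "x2")
  ds$manifest <- rbind(ds$manifest, m)
  s <- score_dataset(ds, min_nucleus_size = 200)
  expect_identical(nrow(s$scores), 2L)
  expect_identical(nrow(s$exclusions), 2L)
  expect_match(s$exclusions$reason, "ioError", all = TRUE)
})
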