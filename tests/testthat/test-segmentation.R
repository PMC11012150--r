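# Nucleus segmentation and locus detection against ground truth and
# constructed geometries.

test_that("degenerate DAPI channels raise NoNucleusFound", {
  expect_error(segment_nucleus(matrix(0, 64, 64)), class = "noNucleusFound")
  expect_error(segment_nucleus(matrix(7, 64, 64)), class = "noNucleusFound")
})

test_that("segmentation recovers the ground-truth nucleus on small scenes", {
  for (s in 1:8) {
    sc <- generate_scene(small_spec(seed = s))
    nuc <- segment_nucleus(sc$stack$channels$dapi, min_size = 200)
    expect_gte(iou(nuc$mask, sc$truth$nucleus_mask), 0.90)
  }
})

test_that("with two disjoint blobs the larger component is returned", {
  img <- matrix(0, 128, 128)
  big <- disc_mask(c(128L, 128L), c(40, 40), 20)
  small <- disc_mask(c(128L, 128L), c(95, 95), 10)
  img[big] <- 200
  img[small] <- 200
  img <- img + matrix(runif(128 * 128), 128)  # break constancy
  nuc <- segment_nucleus(img, min_size = 50, smoothing_sigma = 1)
  expect_gt(iou(nuc$mask, big), 0.8)
  expect_lt(sum(nuc$mask & small), 5)
})

test_that("segmentation is invariant to intensity scaling", {
  sc <- generate_scene(small_spec(seed = 11))
  m1 <- segment_nucleus(sc$stack$channels$dapi, min_size = 200)
  m2 <- segment_nucleus(sc$stack$channels$dapi * 7.3, min_size = 200)
  expect_identical(m1$mask, m2$mask)
})

test_that("locus detection errors on empty red and finds planted blobs", {
  sc <- generate_scene(small_spec(seed = 2))
  nuc <- segment_nucleus(sc$stack$channels$dapi, min_size = 200)
  expect_error(detect_locus(array(0, dim(nuc$mask)), nuc),
               class = "noLocusFound")

  # two planted Gaussian blobs inside the nucleus, peaks 100 and 300
  g <- bifor:::coord_grids(dim(nuc$mask))
  ctr <- nuc$centroid
  blob <- function(c0, amp) amp * exp(-0.5 * (((g[[1]] - c0[1]) / 2)^2 +
                                                ((g[[2]] - c0[2]) / 2)^2))
  red <- blob(ctr + c(-8, -8), 100) + blob(ctr + c(10, 6), 300)
  # a 0.98 quantile keeps enough voxels that both blobs survive thresholding
  expect_warning(roi <- detect_locus(red, nuc, threshold_quantile = 0.98),
                 "2 candidate foci")
  expect_identical(roi$n_candidate_foci, 2L)
  # selected focus contains the exhaustively located brightest voxel
  peak_idx <- which(red == max(red[nuc$mask]), arr.ind = TRUE)[1, ]
  expect_true(roi$mask[peak_idx[1], peak_idx[2]])
  expect_equal(roi$peak_red_intensity, max(red[nuc$mask]))
})

test_that("locus centroid matches ground truth within 2 voxels", {
  for (s in 1:8) {
    sc <- generate_scene(small_spec(seed = 20 + s))
    nuc <- segment_nucleus(sc$stack$channels$dapi, min_size = 200)
    roi <- suppressWarnings(detect_locus(sc$stack$channels$red, nuc))
    err <- sqrt(sum((roi$centroid - sc$truth$locus_center)^2))
    expect_lte(err, 2)
    expect_true(all(nuc$mask[roi$mask]))
  }
})

test_that("raising the threshold quantile never grows the selected focus", {
  sc <- generate_scene(small_spec(seed = 31))
  nuc <- segment_nucleus(sc$stack$channels$dapi, min_size = 200)
  prev <- NULL
  for (q in c(0.98, 0.99, 0.995, 0.999)) {
    roi <- suppressWarnings(
      detect_locus(sc$stack$channels$red, nuc, threshold_quantile = q,
                   dilation_radius = 0))
    if (!is.null(prev)) expect_true(all(prev[roi$mask]))
    prev <- roi$mask
  }
})

test_that("dilation radius grows the ROI and locus max monotonically", {
  sc <- generate_scene(small_spec(seed = 17, enrichment_beta = 1.5))
  nuc <- segment_nucleus(sc$stack$channels$dapi, min_size = 200)
  sizes <- c(); lmax <- c()
  prev <- NULL
  for (r in 0:3) {
    roi <- suppressWarnings(
      detect_locus(sc$stack$channels$red, nuc, dilation_radius = r))
    if (!is.null(prev)) expect_true(all(roi$mask[prev]))
    prev <- roi$mask
    sizes <- c(sizes, sum(roi$mask))
    lmax <- c(lmax, enrichment_ratio(sc$stack$channels$green, roi,
                                     nuc)$locus_max)
  }
  expect_true(all(diff(sizes) >= 0))
  expect_true(all(diff(lmax) >= 0))
})
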