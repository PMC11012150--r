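# Scene generator: geometry, determinism, noise statistics, presets.

test_that("spec validation rejects out-of-bounds geometry and parameters", {
  expect_error(scene_spec(locus_center = c(2, 2)), class = "invalidSpec")
  expect_error(scene_spec(shape = c(64, 64), nucleus_axes = c(40, 40)),
               class = "invalidSpec")
  expect_error(scene_spec(enrichment_beta = -1), class = "invalidSpec")
  expect_error(scene_spec(green_band_coupling = 1.2), class = "invalidSpec")
  expect_s3_class(small_spec(), "scene_spec")
})

test_that("zero-amplitude, zero-noise scene is all-zero but masks are emitted", {
  sc <- generate_scene(small_spec(dapi_amplitude = 0, locus_amplitude = 0,
                                  locus_amplitude_green_bg = 0,
                                  read_noise_sd = 0))
  for (ch in sc$stack$channels) expect_true(all(ch == 0))
  expect_gt(sum(sc$truth$nucleus_mask), 0)
  expect_gt(sum(sc$truth$locus_mask), 0)
  expect_true(all(sc$truth$nucleus_mask[sc$truth$locus_mask]))
})

test_that("identical specs regenerate bit-identical scenes", {
  a <- generate_scene(small_spec(seed = 42L))
  b <- generate_scene(small_spec(seed = 42L))
  expect_identical(a, b)
  c <- generate_scene(small_spec(seed = 43L))
  expect_false(identical(a$stack$channels$green, c$stack$channels$green))
})

test_that("locus mask is contained in the nucleus mask across random scenes", {
  for (s in 1:10) {
    spec <- small_spec(seed = s,
                       locus_center = c(48, 48) +
                         round(10 * c(cos(s), sin(s))))
    sc <- generate_scene(spec)
    expect_true(all(sc$truth$nucleus_mask[sc$truth$locus_mask]))
  }
})

test_that("under the null the locus region is not green-enriched", {
  # compare mean green inside the locus mask to a mirrored off-locus region
  diffs <- vapply(1:50, function(s) {
    spec <- small_spec(seed = s, enrichment_beta = 0)
    sc <- generate_scene(spec)
    centre <- (spec$shape + 1) / 2
    mirror <- 2 * centre - spec$locus_center
    g <- bifor:::coord_grids(spec$shape)
    r2 <- ((g[[1]] - mirror[1]) / spec$locus_sigma[1])^2 +
      ((g[[2]] - mirror[2]) / spec$locus_sigma[2])^2
    off <- (r2 <= 4) & sc$truth$nucleus_mask
    mean(sc$stack$channels$green[sc$truth$locus_mask]) -
      mean(sc$stack$channels$green[off])
  }, 0)
  ci <- stats::t.test(diffs)$conf.int
  expect_lt(ci[1], 0)
  expect_gt(ci[2], 0)
})

test_that("enrichment is an exact multiplicative construction before noise", {
  s0 <- generate_scene(small_spec(seed = 9L, enrichment_beta = 0))
  s2 <- generate_scene(small_spec(seed = 9L, enrichment_beta = 2))
  lm0 <- max(s0$truth$clean$green[s0$truth$locus_mask])
  lm2 <- max(s2$truth$clean$green[s2$truth$locus_mask])
  expect_identical(lm2, 3 * lm0)
  # away from the locus the pre-enrichment background is shared
  expect_identical(s0$truth$green_background, s2$truth$green_background)
})

test_that("shot noise is Poisson: variance tracks the mean for flat scenes", {
  vals <- c()
  for (s in 1:8) {
    sc <- generate_scene(small_spec(seed = s, band_contrast = 0,
                                    green_contrast = 0, read_noise_sd = 0,
                                    enrichment_beta = 0))
    flat <- abs(sc$truth$clean$green - 100) < 1e-9  # PSF-untouched interior
    vals <- c(vals, sc$stack$channels$green[flat])
  }
  expect_gte(length(vals), 1e4)
  expect_lt(abs(var(vals) / mean(vals) - 1), 0.1)
})

test_that("condition presets encode the experiment's contrasts", {
  enriched <- c("SCR_EXD_WT", "SCR_EXD_CONS", "UBX_EXD_CONS")
  null_conds <- c("UBX_EXD_WT", "SCR_ALONE_WT", "UBX_ALONE_WT", "SCR_EXD_MUT")
  for (p in enriched) {
    expect_gt(condition_preset(p)$overrides$enrichment_beta, 0)
  }
  for (p in null_conds) {
    expect_identical(condition_preset(p)$overrides$enrichment_beta, 0)
  }
  expect_identical(
    condition_preset("UBX_EXD_WT")$overrides$locus_amplitude_green_bg,
    3 * condition_preset("SCR_EXD_WT")$overrides$locus_amplitude_green_bg)
  expect_lt(condition_preset("SCR_EXD_MUT")$overrides$locus_amplitude,
            condition_preset("SCR_EXD_WT")$overrides$locus_amplitude)
  expect_error(condition_preset("NO_SUCH"), class = "unknownCondition")
})

test_that("condition datasets are seeded, jittered and carry ground truth", {
  ds0 <- generate_condition_dataset("SCR_EXD_WT", 0, 3, seed = 1)
  expect_identical(nrow(ds0$manifest), 0L)

  base <- scene_spec(shape = c(96L, 96L), locus_sigma = 2)
  ds1 <- generate_condition_dataset("SCR_EXD_MUT", 3, 2, seed = 7,
                                    base_spec = base)
  ds2 <- generate_condition_dataset("SCR_EXD_MUT", 3, 2, seed = 7,
                                    base_spec = base)
  expect_identical(ds1, ds2)
  expect_true(all(ds1$manifest$beta_true == 0))
  expect_identical(sort(unique(ds1$manifest$replicate)), c(1L, 2L))
  # jitter: nucleus sizes differ between scenes
  sizes <- vapply(ds1$scenes, function(s) sum(s$truth$nucleus_mask), 0L)
  expect_gt(length(unique(sizes)), 1L)
})

test_that("3D scenes generate, segment and score end to end", {
  spec <- scene_spec(shape = c(16L, 96L, 96L), nucleus_axes = c(4, 32, 26),
                     locus_center = c(8.5, 55, 40), locus_sigma = c(1.5, 2, 2),
                     psf_sigma = c(1, 0.85, 0.85), enrichment_beta = 1.5,
                     seed = 3L)
  sc <- generate_scene(spec)
  expect_identical(dim(sc$stack$channels$green), c(16L, 96L, 96L))
  nuc <- segment_nucleus(sc$stack$channels$dapi, min_size = 200)
  roi <- suppressWarnings(detect_locus(sc$stack$channels$red, nuc))
  e <- enrichment_ratio(sc$stack$channels$green, roi, nuc)
  expect_true(e$value > 0 && e$value <= 1)
  expect_true(all(nuc$mask[roi$mask]))
  expect_lt(sqrt(sum((roi$centroid - spec$locus_center)^2)), 2.5)
})
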