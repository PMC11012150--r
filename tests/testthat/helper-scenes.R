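# Shared fixtures: all test inputs are generated in code.

# Small scene for unit tests; acceptance tests use the full-size defaults.
small_spec <- function(seed = 1L, ...) {
  scene_spec(shape = c(96L, 96L), locus_sigma = 2, seed = seed, ...)
}

iou <- function(a, b) sum(a & b) / sum(a | b)

# Region containers built directly from masks, bypassing segmentation.
make_nucleus <- function(mask) {
  structure(list(mask = mask, size = sum(mask),
                 centroid = bifor:::mask_centroid(mask),
                 on_border = bifor:::touches_border(mask)),
            class = "nucleus_mask")
}

make_locus <- function(mask, peak = NA_real_, n_foci = 1L) {
  structure(list(mask = mask, centroid = bifor:::mask_centroid(mask),
                 peak_red_intensity = peak,
                 n_candidate_foci = as.integer(n_foci)),
            class = "locus_roi")
}

# Independent brute-force oracle for the strict-max enrichment ratio:
# explicit scan over the two voxel lists, no vectorised max.
brute_force_ratio <- function(green, locus_mask, nucleus_mask) {
  ml <- -Inf
  for (i in which(locus_mask)) if (green[i] > ml) ml <- green[i]
  mn <- -Inf
  for (i in which(nucleus_mask)) if (green[i] > mn) mn <- green[i]
  ml / mn
}

# Independent exhaustive permutation oracle: enumerate every assignment of
# the pooled values into a group of size n_a via bitmasks.
enumerate_perm_p <- function(a, b) {
  pool <- c(a, b)
  n <- length(pool)
  n_a <- length(a)
  obs <- mean(a) - mean(b)
  count <- 0L
  total <- 0L
  for (bits in 0:(2^n - 1)) {
    sel <- which(bitwAnd(bitwShiftR(bits, 0:(n - 1)), 1L) == 1L)
    if (length(sel) != n_a) next
    total <- total + 1L
    stat <- mean(pool[sel]) - mean(pool[-sel])
    if (abs(stat) >= abs(obs) - 1e-12) count <- count + 1L
  }
  count / total
}

# A disc-shaped blob mask centred at `ctr` with radius r.
disc_mask <- function(shape, ctr, r) {
  g <- bifor:::coord_grids(shape)
  (g[[1]] - ctr[1])^2 + (g[[2]] - ctr[2])^2 <= r^2
}
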