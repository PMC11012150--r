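# Internal helpers: classed errors, seeded RNG scoping, separable Gaussian
# blur and n-d morphology shared by the generator and the segmentation stage.

bifor_error <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "bifor_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a private RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library code never perturbs user simulations.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive independent child seeds from a master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

# Separable Gaussian blur of a 2D or 3D array; `sigma` recycled per axis.
# Used both as the simulator PSF and as pre-segmentation smoothing so the 2D
# and 3D code paths are identical.
gaussian_blur <- function(x, sigma) {
  d <- dim(x)
  nd <- length(d)
  sigma <- rep_len(sigma, nd)
  storage.mode(x) <- "double"
  for (ax in seq_len(nd)) {
    if (sigma[ax] <= 0) next
    x <- conv_axis_cpp(x, d, ax, gaussian_kernel(sigma[ax]))
  }
  array(x, dim = d)
}

# Linear-interpolation matrix mapping a coarse grid (stride s, m points) onto
# 1..n; rows are hat-function weights.
interp_matrix <- function(n, s, m) {
  t <- seq_len(n)
  j <- pmin((t - 1) / s + 1, m - 1e-9)
  j0 <- floor(j)
  w <- j - j0
  W <- matrix(0, n, m)
  W[cbind(t, j0)] <- 1 - w
  W[cbind(t, pmin(j0 + 1, m))] <- W[cbind(t, pmin(j0 + 1, m))] + w
  W
}

# Standardised smooth Gaussian random field (mean 0, sd 1). For 2D fields
# with a wide kernel the field is drawn on a stride-4 coarse grid, blurred
# there and bilinearly upsampled, which is statistically equivalent at these
# correlation lengths and an order of magnitude faster.
smooth_field <- function(d, sigma) {
  nd <- length(d)
  s <- 4L
  if (nd == 2L && sigma >= 3 && all(d >= 4L * s)) {
    m <- ceiling((d - 1L) / s) + 1L
    z <- gaussian_blur(matrix(stats::rnorm(prod(m)), m[1], m[2]), sigma / s)
    z <- interp_matrix(d[1], s, m[1]) %*% z %*% t(interp_matrix(d[2], s, m[2]))
  } else {
    z <- gaussian_blur(array(stats::rnorm(prod(d)), dim = d), sigma)
  }
  z <- z - mean(z)
  array(z / max(stats::sd(z), 1e-12), dim = d)
}

# Voxel coordinate grids (1-based), one matrix/array per axis.
coord_grids <- function(shape) {
  nd <- length(shape)
  lapply(seq_len(nd), function(ax) {
    v <- seq_len(shape[ax])
    rep_dims <- rep(1L, nd)
    rep_dims[ax] <- shape[ax]
    array(rep(v, each = prod(shape[seq_len(ax - 1L)])), dim = shape)
  })
}

# Connected components of a logical 2D/3D array (face connectivity).
# EBImage::bwlabel covers the 2D case; the 3D case is a hand-rolled BFS since
# no installed labeller handles volumes.
label_components <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2L) {
    lab <- EBImage::bwlabel(mask * 1)
    return(array(as.integer(lab), dim = d))
  }
  lab <- array(0L, dim = d)
  nvox <- length(mask)
  strides <- c(1L, d[1], d[1] * d[2])
  current <- 0L
  queue <- integer(nvox)
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    current <- current + 1L
    lab[start] <- current
    queue[1] <- start
    head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      v0 <- v - 1L
      z <- v0 %/% strides[3]
      rem <- v0 %% strides[3]
      y <- rem %/% strides[2]
      xx <- rem %% strides[2]
      pos <- c(xx, y, z)  # 0-based along dim1, dim2, dim3
      for (ax in 1:3) {
        for (s in c(-1L, 1L)) {
          p <- pos[ax] + s
          if (p < 0L || p >= d[ax]) next
          nb <- v + s * strides[ax]
          if (mask[nb] && lab[nb] == 0L) {
            lab[nb] <- current
            tail <- tail + 1L
            queue[tail] <- nb
          }
        }
      }
    }
  }
  lab
}

# Binary dilation by a Euclidean ball of integer radius; shift-accumulate over
# in-ball offsets, valid for 2D and 3D. Work is restricted to the bounding
# box of the foreground (padded by the radius), so dilating a small ROI in a
# large volume stays cheap.
dilate_ball <- function(mask, radius) {
  radius <- as.integer(round(radius))
  if (radius <= 0L || !any(mask)) return(mask)
  d <- dim(mask)
  nd <- length(d)
  idx <- which(mask, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - radius, 1L)
  hi <- pmin(apply(idx, 2, max) + radius, d)
  box <- lapply(seq_len(nd), function(ax) lo[ax]:hi[ax])
  sub <- do.call(`[`, c(list(mask), box, list(drop = FALSE)))
  sub <- dilate_ball_full(sub, radius)
  out <- array(FALSE, dim = d)
  do.call(`[<-`, c(list(out), box, list(value = sub)))
}

dilate_ball_full <- function(mask, radius) {
  d <- dim(mask)
  nd <- length(d)
  offs <- as.matrix(do.call(expand.grid, rep(list(-radius:radius), nd)))
  offs <- offs[rowSums(offs^2) <= radius^2, , drop = FALSE]
  out <- array(FALSE, dim = d)
  for (i in seq_len(nrow(offs))) {
    src <- dst <- vector("list", nd)
    ok <- TRUE
    for (ax in seq_len(nd)) {
      o <- offs[i, ax]
      s1 <- max(1L, 1L - o); s2 <- min(d[ax], d[ax] - o)
      if (s1 > s2) { ok <- FALSE; break }
      src[[ax]] <- s1:s2
      dst[[ax]] <- (s1 + o):(s2 + o)
    }
    if (!ok) next
    piece <- do.call(`[`, c(list(mask), src, list(drop = FALSE)))
    prev <- do.call(`[`, c(list(out), dst, list(drop = FALSE)))
    out <- do.call(`[<-`, c(list(out), dst, list(value = prev | piece)))
  }
  out
}

# Fill interior holes: EBImage::fillHull per 2D plane (slice-wise for 3D).
fill_holes <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2L) {
    return(array(EBImage::fillHull(mask * 1) > 0, dim = d))
  }
  for (z in seq_len(d[1])) {
    mask[z, , ] <- EBImage::fillHull(mask[z, , ] * 1) > 0
  }
  mask
}

mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  colMeans(idx)
}

touches_border <- function(mask) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(FALSE)
  any(idx == 1L) || any(sweep(idx, 2, d, `==`))
}
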