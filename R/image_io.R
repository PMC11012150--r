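# Multi-channel stack and manifest I/O. Stacks are plain TIFFs (multi-page:
# channels, or channels x Z for volumes) with a JSON sidecar recording the
# channel roles, axis order and voxel size; manifests are CSV.

CHANNEL_ROLES <- c("dapi", "red", "green")

#' Multi-channel image stack
#'
#' Container for aligned intensity volumes, one per channel role
#' (`dapi` = chromatin counterstain, `red` = ParB-mCherry locus label,
#' `green` = BiFC or immunostaining signal). Axis order is (Z,)Y,X with
#' 1-based voxel coordinates; intensities are non-negative photons (floats in
#' memory, 16-bit unsigned on disk).
#'
#' @param channels Named list of non-negative numeric arrays sharing one
#'   shape; names must be among `dapi`, `red`, `green`.
#' @param voxel_size Micrometres per voxel per axis (recycled).
#' @param saturated Named logical per channel: whether values were clipped on
#'   write.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, voxel_size = 0.06, saturated = NULL) {
  if (is.null(names(channels)) || !all(names(channels) %in% CHANNEL_ROLES)) {
    bifor_error("invalidStack",
                sprintf("channels must be named among {%s}",
                        paste(CHANNEL_ROLES, collapse = ", ")))
  }
  channels <- lapply(channels, function(ch) {
    if (is.null(dim(ch))) bifor_error("invalidStack", "channels must be 2D or 3D arrays")
    if (!length(dim(ch)) %in% c(2L, 3L)) {
      bifor_error("invalidStack", "channels must be 2D or 3D arrays")
    }
    storage.mode(ch) <- "double"
    ch
  })
  shapes <- lapply(channels, dim)
  if (length(unique(shapes)) != 1L) {
    bifor_error("invalidStack", "all channels must share an identical shape")
  }
  if (any(vapply(channels, function(ch) any(ch < 0), TRUE))) {
    bifor_error("invalidStack", "intensities must be >= 0")
  }
  nd <- length(shapes[[1]])
  if (is.null(saturated)) {
    saturated <- stats::setNames(rep(FALSE, length(channels)), names(channels))
  }
  structure(list(channels = channels,
                 voxel_size = rep_len(voxel_size, nd),
                 axes_order = if (nd == 2L) "YX" else "ZYX",
                 saturated = saturated),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("image_stack: channels {%s}, %s (%s), voxel %s um\n",
              paste(names(x$channels), collapse = ","),
              paste(d, collapse = "x"), x$axes_order,
              paste(signif(x$voxel_size, 3), collapse = "x")))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$channels[[1]])

#' Write a stack as a 16-bit multi-page TIFF
#'
#' Channels are written as consecutive pages (for 3D: channel-major, all Z
#' planes of a channel together). Values are rounded half-up to integers and
#' clipped to [0, 65535]; if clipping occurred the channel's `saturated` flag
#' is set and returned. A JSON sidecar `<path>.json` records channel order,
#' axis order, shape, voxel size and saturation flags.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return Invisibly, the stack with updated `saturated` flags.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$channels[[1]])
  nd <- length(d)
  pages <- list()
  sat <- stack$saturated
  for (role in names(stack$channels)) {
    ch <- floor(stack$channels[[role]] + 0.5)
    if (any(ch > 65535)) {
      sat[role] <- TRUE
      ch <- pmin(ch, 65535)
    }
    if (nd == 2L) {
      pages <- c(pages, list(ch / 65535))
    } else {
      pages <- c(pages, lapply(seq_len(d[1]), function(z) ch[z, , ] / 65535))
    }
  }
  ok <- tryCatch(
    tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                    compression = "deflate"),
    error = function(e) bifor_error("ioError", conditionMessage(e))
  )
  meta <- list(channel_order = names(stack$channels),
               axes_order = stack$axes_order, shape = d,
               voxel_size = stack$voxel_size,
               saturated = as.list(sat))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  stack$saturated <- sat
  invisible(stack)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read a multi-channel TIFF stack
#'
#' When a JSON sidecar written by [write_stack()] is present the channel
#' roles, axis order and voxel size are recovered from it; otherwise
#' `channel_order` declares the roles and the pages are interpreted as one
#' 2D plane per channel (or `channels x Z` when `nz` is given).
#'
#' @param path TIFF path.
#' @param channel_order Character vector of roles for the stored channels,
#'   in page order; ignored when a sidecar is present.
#' @param nz Number of Z planes per channel for sidecar-less 3D files.
#' @param voxel_size Fallback voxel size when no sidecar is present.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, channel_order = c("dapi", "red", "green"),
                       nz = 1L, voxel_size = 0.06) {
  if (!file.exists(path)) {
    bifor_error("ioError", sprintf("no such file: %s", path))
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- NULL
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    channel_order <- meta$channel_order
    nz <- if (identical(meta$axes_order, "ZYX")) meta$shape[1] else 1L
    voxel_size <- meta$voxel_size
  }
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, TRUE))) {
    bifor_error("ioError", "only single-sample (grayscale) TIFF pages are supported")
  }
  nch <- length(channel_order)
  if (length(pages) != nch * nz) {
    bifor_error("channelMismatch",
                sprintf("file has %d page(s) but %d channel(s) x %d plane(s) were declared",
                        length(pages), nch, nz))
  }
  channels <- stats::setNames(vector("list", nch), channel_order)
  for (i in seq_len(nch)) {
    chunk <- pages[((i - 1L) * nz + 1L):(i * nz)]
    if (nz == 1L) {
      channels[[i]] <- chunk[[1]] * 1.0
    } else {
      arr <- array(0, dim = c(nz, dim(chunk[[1]])))
      for (z in seq_len(nz)) arr[z, , ] <- chunk[[z]]
      channels[[i]] <- arr
    }
  }
  sat <- if (!is.null(meta)) {
    stats::setNames(unlist(meta$saturated)[channel_order], channel_order)
  } else NULL
  image_stack(channels, voxel_size = voxel_size, saturated = sat)
}

# Boolean mask as a compact single-channel 8-bit TIFF (audit output).
write_mask_tiff <- function(mask, path) {
  d <- dim(mask)
  pages <- if (length(d) == 2L) {
    list(mask * 1.0)
  } else {
    lapply(seq_len(d[1]), function(z) mask[z, , ] * 1.0)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "deflate")
  invisible(path)
}

empty_manifest <- function() {
  data.frame(scene_id = character(), condition = character(),
             replicate = integer(), path = character(),
             beta_true = numeric(), stringsAsFactors = FALSE)
}

validate_manifest <- function(manifest) {
  required <- c("scene_id", "condition", "replicate", "path")
  missing <- setdiff(required, names(manifest))
  if (length(missing)) {
    bifor_error("invalidManifest",
                sprintf("manifest lacks column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(manifest$scene_id)) {
    dup <- unique(manifest$scene_id[duplicated(manifest$scene_id)])
    bifor_error("invalidManifest",
                sprintf("duplicate scene_id(s): %s",
                        paste(utils::head(dup, 3), collapse = ", ")))
  }
  for (cond in unique(manifest$condition)) {
    reps <- sort(unique(manifest$replicate[manifest$condition == cond]))
    if (length(reps) && !identical(as.integer(reps), seq_len(max(reps)))) {
      bifor_error("invalidManifest",
                  sprintf("replicate ids for '%s' are not a contiguous 1..R range", cond))
    }
  }
  manifest
}

#' Read / write a dataset manifest
#'
#' The manifest maps each scene to its condition, biological replicate and
#' stack file, optionally carrying the ground-truth enrichment `beta_true`
#' for simulated data. `scene_id` must be unique and replicate ids must form
#' a contiguous `1..R` range within each condition.
#'
#' @param path CSV path.
#' @param manifest Manifest `data.frame`.
#' @return `read_manifest` returns the validated manifest;
#'   `write_manifest` invisibly returns `path`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    bifor_error("ioError", sprintf("no such file: %s", path))
  }
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(c("scene_id", "condition", "path"), names(m))) {
    m[[col]] <- as.character(m[[col]])
  }
  if ("replicate" %in% names(m)) m$replicate <- as.integer(m$replicate)
  validate_manifest(m)
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
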