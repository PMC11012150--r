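#' Parametric description of a synthetic nucleus scene
#'
#' A `scene_spec` describes one simulated polytene nucleus: an elliptical
#' (2D) or ellipsoidal (3D) nucleus with banded DAPI texture, a single
#' ParB-mCherry locus focus rendered as a Gaussian blob, and a green (BiFC or
#' immunostaining) channel whose background follows the DAPI bands only
#' partially and which may be multiplicatively enriched at the locus.
#' All geometric quantities are in voxels with 1-based coordinates and axis
#' order (Z,)Y,X; intensities are in expected photons.
#'
#' @param shape Integer voxel dimensions, length 2 (Y,X) or 3 (Z,Y,X).
#' @param voxel_size Micrometres per voxel per axis (recycled).
#' @param nucleus_axes Ellipsoid semi-axes in voxels, one per axis.
#' @param n_bands Number of polytene bands across the nucleus.
#' @param band_contrast Dimensionless band/interband contrast, >= 0. At 0 the
#'   DAPI (and any band-coupled green) texture is flat.
#' @param dapi_amplitude Mean DAPI photon level inside the nucleus.
#' @param locus_center Voxel coordinates of the locus focus; must lie inside
#'   the nucleus ellipsoid. Default: offset from the nucleus centre by 30% of
#'   the semi-axes in-plane.
#' @param locus_sigma Per-axis Gaussian widths of the locus focus (voxels).
#' @param locus_amplitude Peak mCherry photon level of the locus focus.
#' @param locus_amplitude_green_bg Baseline green photon level in the nucleus.
#' @param green_band_coupling Fraction in [0,1] of the green background that
#'   follows the DAPI bands; the rest is a band-independent smooth texture.
#' @param green_contrast Dimensionless contrast of the band-independent green
#'   texture, >= 0 (0 gives a flat component).
#' @param enrichment_beta Multiplicative green boost at the locus, >= 0; the
#'   green channel is multiplied by (1 + enrichment_beta * locus profile),
#'   so 0 is the no-enrichment null.
#' @param psf_sigma Per-axis Gaussian PSF sigma in voxels. The default 0.85
#'   at the default 60 nm pixel gives a PSF FWHM of about 120 nm.
#' @param read_noise_sd Gaussian read-noise standard deviation (photons).
#' @param seed Integer seed; identical specs (including seed) regenerate
#'   bit-identical scenes.
#'
#' @return An object of class `scene_spec` (a validated named list).
#' @seealso [generate_scene()], [condition_preset()]
#' @export
scene_spec <- function(shape = c(256L, 256L),
                       voxel_size = 0.06,
                       nucleus_axes = NULL,
                       n_bands = 12,
                       band_contrast = 0.8,
                       dapi_amplitude = 200,
                       locus_center = NULL,
                       locus_sigma = 3,
                       locus_amplitude = 800,
                       locus_amplitude_green_bg = 100,
                       green_band_coupling = 0.6,
                       green_contrast = 0.4,
                       enrichment_beta = 0,
                       psf_sigma = 0.85,
                       read_noise_sd = 3,
                       seed = 1L) {
  shape <- as.integer(shape)
  nd <- length(shape)
  if (!nd %in% c(2L, 3L)) {
    bifor_error("invalidSpec", "shape must have length 2 (Y,X) or 3 (Z,Y,X)")
  }
  if (is.null(nucleus_axes)) {
    inplane <- c(0.35, 0.275) * shape[(nd - 1L):nd]
    nucleus_axes <- if (nd == 2L) inplane else c(0.3 * shape[1], inplane)
  }
  nucleus_axes <- rep_len(nucleus_axes, nd)
  voxel_size <- rep_len(voxel_size, nd)
  locus_sigma <- rep_len(locus_sigma, nd)
  psf_sigma <- rep_len(psf_sigma, nd)
  centre <- (shape + 1) / 2
  if (is.null(locus_center)) {
    off <- 0.3 * nucleus_axes
    if (nd == 3L) off[1] <- 0
    locus_center <- centre + off * c(rep(1, nd - 1), -1)
  }
  spec <- structure(list(
    shape = shape, voxel_size = voxel_size, nucleus_axes = nucleus_axes,
    n_bands = n_bands, band_contrast = band_contrast,
    dapi_amplitude = dapi_amplitude,
    locus_center = as.numeric(locus_center), locus_sigma = locus_sigma,
    locus_amplitude = locus_amplitude,
    locus_amplitude_green_bg = locus_amplitude_green_bg,
    green_band_coupling = green_band_coupling, green_contrast = green_contrast,
    enrichment_beta = enrichment_beta, psf_sigma = psf_sigma,
    read_noise_sd = read_noise_sd, seed = as.integer(seed)
  ), class = "scene_spec")
  validate_scene_spec(spec)
}

#' @rdname scene_spec
#' @param spec A `scene_spec` to validate.
#' @export
validate_scene_spec <- function(spec) {
  with(spec, {
    nd <- length(shape)
    nonneg <- c(band_contrast, dapi_amplitude, locus_sigma, locus_amplitude,
                locus_amplitude_green_bg, green_contrast, enrichment_beta,
                psf_sigma, read_noise_sd)
    if (any(!is.finite(nonneg)) || any(nonneg < 0)) {
      bifor_error("invalidSpec", "amplitudes, sigmas, contrasts and noise parameters must be finite and >= 0")
    }
    if (green_band_coupling < 0 || green_band_coupling > 1) {
      bifor_error("invalidSpec", "green_band_coupling must lie in [0, 1]")
    }
    if (length(locus_center) != nd) {
      bifor_error("invalidSpec", "locus_center must have one coordinate per axis")
    }
    centre <- (shape + 1) / 2
    r2 <- sum(((locus_center - centre) / nucleus_axes)^2)
    if (r2 >= 1) {
      bifor_error("invalidSpec", "locus_center lies outside the nucleus ellipsoid")
    }
    margin <- nucleus_axes + 3 * psf_sigma
    if (any(centre - margin < 1) || any(centre + margin > shape)) {
      bifor_error("invalidSpec", "shape too small: nucleus plus 3*psf_sigma margin exceeds the image")
    }
  })
  spec
}

#' @export
print.scene_spec <- function(x, ...) {
  nd <- length(x$shape)
  cat(sprintf("scene_spec: %s scene %s, nucleus semi-axes (%s) vx\n",
              if (nd == 2L) "2D" else "3D",
              paste(x$shape, collapse = "x"),
              paste(signif(x$nucleus_axes, 3), collapse = ", ")))
  cat(sprintf("  locus at (%s), sigma (%s) vx, amplitude %g; green bg %g, beta %g\n",
              paste(signif(x$locus_center, 4), collapse = ", "),
              paste(signif(x$locus_sigma, 3), collapse = ", "),
              x$locus_amplitude, x$locus_amplitude_green_bg, x$enrichment_beta))
  cat(sprintf("  PSF sigma (%s) vx, read noise %g, seed %d\n",
              paste(signif(x$psf_sigma, 3), collapse = ", "),
              x$read_noise_sd, x$seed))
  invisible(x)
}

# Baseline photon levels shared by the presets. The Ubx/Exd BiFC background is
# three times the Scr/Exd level, and the MUT construct's ParB-mCherry focus is
# rendered at half the wild-type amplitude (it is reported as usually dimmer).
.preset_table <- function() {
  base_green <- 100
  list(
    SCR_EXD_WT   = list(enrichment_beta = 1.5, locus_amplitude = 800,
                        locus_amplitude_green_bg = base_green),
    UBX_EXD_WT   = list(enrichment_beta = 0,   locus_amplitude = 800,
                        locus_amplitude_green_bg = 3 * base_green),
    SCR_ALONE_WT = list(enrichment_beta = 0,   locus_amplitude = 800,
                        locus_amplitude_green_bg = base_green),
    UBX_ALONE_WT = list(enrichment_beta = 0,   locus_amplitude = 800,
                        locus_amplitude_green_bg = base_green),
    SCR_EXD_MUT  = list(enrichment_beta = 0,   locus_amplitude = 400,
                        locus_amplitude_green_bg = base_green),
    SCR_EXD_CONS = list(enrichment_beta = 1.5, locus_amplitude = 800,
                        locus_amplitude_green_bg = base_green),
    UBX_EXD_CONS = list(enrichment_beta = 1.5, locus_amplitude = 800,
                        locus_amplitude_green_bg = 3 * base_green)
  )
}

#' Experimental condition presets
#'
#' Each preset names a protein/enhancer combination of the BiFOR validation
#' experiment and carries the scene-spec overrides that emulate it: whether
#' green signal is enriched at the labelled locus (`enrichment_beta > 0`,
#' used for Scr/Exd on the wild-type enhancer and for Hox/Exd pairs on the
#' consensus variant), the global green level (Ubx/Exd BiFC is three times
#' the Scr/Exd level), and the locus label amplitude (halved for the
#' binding-site mutant, whose ParB focus is typically dimmer).
#'
#' @param name One of `names(condition_presets())`.
#' @param ... Further `scene_spec` overrides applied on top of the preset.
#' @return A `condition_preset`: the preset name plus its spec overrides.
#' @export
condition_preset <- function(name, ...) {
  tab <- .preset_table()
  if (!name %in% names(tab)) {
    bifor_error("unknownCondition",
                sprintf("unknown preset '%s'; available: %s",
                        name, paste(names(tab), collapse = ", ")))
  }
  overrides <- utils::modifyList(tab[[name]], list(...))
  structure(list(name = name, overrides = overrides),
            class = "condition_preset")
}

#' @rdname condition_preset
#' @export
condition_presets <- function() {
  names(.preset_table())
}

#' @export
print.condition_preset <- function(x, ...) {
  ov <- vapply(x$overrides, function(v) paste(signif(unlist(v), 4), collapse = ","), "")
  cat(sprintf("condition_preset '%s': %s\n", x$name,
              paste(sprintf("%s=%s", names(ov), ov), collapse = ", ")))
  invisible(x)
}
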