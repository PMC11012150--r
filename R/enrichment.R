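# The per-nucleus enrichment statistic: maximum green intensity within the
# locus ROI divided by the maximum over the whole nucleus. Because the locus
# lies inside the nucleus the ratio is bounded in (0, 1], and equals 1 exactly
# when the locus contains a nucleus-global maximum voxel.

#' Per-nucleus locus-enrichment ratio
#'
#' Computes `max(green | locus) / max(green | nucleus)` (estimator
#' `"strict_max"`, the default) or the same ratio with both maxima replaced
#' by the `q`-quantile of the respective voxel sets (estimator `"quantile"`,
#' more robust on Poisson-noisy data where a literal maximum is an extreme
#' order statistic). The whole-nucleus maximum includes the locus region,
#' which is what bounds the ratio by 1.
#'
#' Optionally the in-nucleus median can be subtracted first (clipped at
#' zero). This is off by default — the plain ratio has no background
#' correction — but is provided because the ratio `(m+c)/(M+c)` drifts
#' towards 1 as a constant offset `c` grows, so background handling changes
#' the statistic's dynamic range.
#'
#' @param green Non-negative intensity array.
#' @param locus A `locus_roi` from [detect_locus()].
#' @param nucleus A `nucleus_mask` from [segment_nucleus()].
#' @param estimator `"strict_max"` or `"quantile"`.
#' @param q Quantile used by the `"quantile"` estimator.
#' @param subtract_median Subtract the in-nucleus median (clipped at zero)
#'   before taking the maxima.
#' @param scene_id,condition,replicate Provenance carried into the result.
#' @return An `enrichment_score`: list with `value`, `locus_max`,
#'   `nucleus_max`, `estimator` and provenance fields.
#' @export
enrichment_ratio <- function(green, locus, nucleus,
                             estimator = c("strict_max", "quantile"),
                             q = 0.999, subtract_median = FALSE,
                             scene_id = NA_character_,
                             condition = NA_character_,
                             replicate = NA_integer_) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(nucleus, "nucleus_mask"), inherits(locus, "locus_roi"))
  if (!any(locus$mask)) {
    bifor_error("emptyLocus", "locus ROI is empty (should be NoLocusFound upstream)")
  }
  if (!all(nucleus$mask[locus$mask])) {
    bifor_error("invalidRegions", "locus ROI is not contained in the nucleus mask")
  }
  g_nuc <- green[nucleus$mask]
  g_loc <- green[locus$mask]
  if (subtract_median) {
    med <- stats::median(g_nuc)
    g_nuc <- pmax(g_nuc - med, 0)
    g_loc <- pmax(g_loc - med, 0)
  }
  if (estimator == "strict_max") {
    locus_max <- max(g_loc)
    nucleus_max <- max(g_nuc)
    est_label <- "strict_max"
  } else {
    locus_max <- stats::quantile(g_loc, q, names = FALSE)
    nucleus_max <- stats::quantile(g_nuc, q, names = FALSE)
    est_label <- sprintf("quantile(%g)", q)
  }
  if (nucleus_max <= 0) {
    bifor_error("degenerateSignal",
                "green channel carries no signal in the nucleus (nucleus max = 0)")
  }
  structure(list(value = locus_max / nucleus_max,
                 locus_max = locus_max, nucleus_max = nucleus_max,
                 estimator = est_label, scene_id = scene_id,
                 condition = condition, replicate = replicate),
            class = "enrichment_score")
}

#' @export
print.enrichment_score <- function(x, ...) {
  cat(sprintf("enrichment_score: %.4f (locus %g / nucleus %g, %s)\n",
              x$value, x$locus_max, x$nucleus_max, x$estimator))
  invisible(x)
}

#' Score every nucleus of a dataset
#'
#' Runs segmentation, locus detection and [enrichment_ratio()] on each scene
#' of a dataset (an in-memory `bifor_dataset` or a manifest whose `path`
#' column points to TIFF stacks). Nuclei are excluded — with the reason
#' recorded — when no nucleus or no locus focus is found, when the nucleus
#' touches the image border (`exclude_border`), or when the file cannot be
#' read; the pipeline continues past per-scene failures and errors only if
#' every scene failed.
#'
#' @param dataset A `bifor_dataset` or a manifest `data.frame`.
#' @param threshold_quantile,dilation_radius Passed to [detect_locus()].
#' @param min_nucleus_size,smoothing_sigma Passed to [segment_nucleus()].
#' @param estimator,q,subtract_median Passed to [enrichment_ratio()].
#' @param exclude_border Drop nuclei whose mask touches the image border.
#' @return A `bifor_scores`: list with `scores` (data.frame: scene_id,
#'   condition, replicate, value, locus_max, nucleus_max, estimator, qc) and
#'   `exclusions` (data.frame: scene_id, reason).
#' @export
score_dataset <- function(dataset,
                          threshold_quantile = 0.995, dilation_radius = 2,
                          min_nucleus_size = 500, smoothing_sigma = 6,
                          estimator = "strict_max", q = 0.999,
                          subtract_median = FALSE, exclude_border = TRUE) {
  if (inherits(dataset, "bifor_dataset")) {
    manifest <- dataset$manifest
    scenes <- dataset$scenes
  } else {
    manifest <- validate_manifest(dataset)
    scenes <- NULL
  }
  rows <- vector("list", nrow(manifest))
  excl <- list()
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$scene_id[i]
    res <- tryCatch({
      stack <- if (!is.null(scenes) && !is.null(scenes[[id]])) {
        scenes[[id]]$stack
      } else {
        read_stack(manifest$path[i])
      }
      nuc <- segment_nucleus(stack$channels$dapi,
                             min_size = min_nucleus_size,
                             smoothing_sigma = smoothing_sigma)
      if (exclude_border && nuc$on_border) {
        bifor_error("borderNucleus", "nucleus touches the image border")
      }
      roi <- suppressWarnings(
        detect_locus(stack$channels$red, nuc,
                     threshold_quantile = threshold_quantile,
                     dilation_radius = dilation_radius)
      )
      sc <- enrichment_ratio(stack$channels$green, roi, nuc,
                             estimator = estimator, q = q,
                             subtract_median = subtract_median,
                             scene_id = id,
                             condition = manifest$condition[i],
                             replicate = manifest$replicate[i])
      data.frame(scene_id = id, condition = manifest$condition[i],
                 replicate = manifest$replicate[i], value = sc$value,
                 locus_max = sc$locus_max, nucleus_max = sc$nucleus_max,
                 estimator = sc$estimator,
                 qc = if (roi$n_candidate_foci > 1L) {
                   sprintf("multi_focus(%d)", roi$n_candidate_foci)
                 } else "ok",
                 stringsAsFactors = FALSE)
    }, bifor_error = function(e) {
      data.frame(scene_id = id,
                 reason = paste0(class(e)[1], ": ", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(scene_id = id,
                 reason = paste0("error: ", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
    if ("reason" %in% names(res)) excl[[length(excl) + 1L]] <- res
    else rows[[i]] <- res
  }
  scores <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(scores)) {
    scores <- data.frame(scene_id = character(), condition = character(),
                         replicate = integer(), value = numeric(),
                         locus_max = numeric(), nucleus_max = numeric(),
                         estimator = character(), qc = character(),
                         stringsAsFactors = FALSE)
  }
  exclusions <- if (length(excl)) do.call(rbind, excl) else {
    data.frame(scene_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  }
  rownames(scores) <- rownames(exclusions) <- NULL
  if (nrow(manifest) > 0 && nrow(scores) == 0) {
    bifor_error("pipelineError", "every scene failed scoring")
  }
  structure(list(scores = scores, exclusions = exclusions),
            class = "bifor_scores")
}

#' @export
print.bifor_scores <- function(x, ...) {
  cat(sprintf("bifor_scores: %d scored nucleus/nuclei, %d excluded\n",
              nrow(x$scores), nrow(x$exclusions)))
  if (nrow(x$scores)) {
    agg <- stats::aggregate(value ~ condition, data = x$scores,
                            FUN = function(v) c(n = length(v),
                                                mean = mean(v),
                                                median = stats::median(v)))
    tab <- data.frame(condition = agg$condition,
                      n = agg$value[, "n"],
                      mean = signif(agg$value[, "mean"], 4),
                      median = signif(agg$value[, "median"], 4))
    print(tab, row.names = FALSE)
  }
  invisible(x)
}
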