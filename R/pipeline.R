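# One-shot orchestration: simulate -> quantify -> compare under a single
# validated, fully serializable configuration, with a run log and a
# figure-style summary plot. All quantitative outputs are CSV; plots
# are advisory.

.config_defaults <- function() {
  list(
    presets = condition_presets(),
    n_nuclei_per_replicate = 10L,
    n_replicates = 3L,
    ndim = 2L,
    seed = 1L,
    channel_order = c("dapi", "red", "green"),
    threshold_quantile = 0.995,
    dilation_radius = 2,
    min_nucleus_size = 500,
    smoothing_sigma = 6,
    estimator = "strict_max",
    quantile_q = 0.999,
    subtract_median = FALSE,
    exclude_border = TRUE,
    test = "mannwhitney",
    n_perm = 10000L,
    holm = FALSE,
    write_images = FALSE,
    comparisons = list(
      c("SCR_EXD_WT", "UBX_EXD_WT"),
      c("SCR_EXD_WT", "SCR_ALONE_WT"),
      c("SCR_EXD_WT", "UBX_ALONE_WT"),
      c("SCR_EXD_WT", "SCR_EXD_MUT"),
      c("SCR_EXD_MUT", "SCR_ALONE_WT"),
      c("SCR_EXD_CONS", "SCR_ALONE_WT"),
      c("UBX_EXD_CONS", "UBX_ALONE_WT"),
      c("SCR_EXD_CONS", "UBX_EXD_CONS")
    )
  )
}

#' Validate a pipeline configuration
#'
#' Fills defaults, rejects unknown keys and checks parameter ranges. The
#' returned config plus its seed is sufficient to replay a run exactly.
#'
#' @param config Named list of overrides (possibly empty).
#' @return A complete, validated config (class `bifor_config`).
#' @export
validate_config <- function(config = list()) {
  if (inherits(config, "bifor_config")) config <- unclass(config)
  defaults <- .config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    bifor_error("invalidConfig",
                sprintf("unknown config key(s): %s",
                        paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config)
  if (!is.null(config$comparisons)) {
    # replace wholesale: modifyList would merge the unnamed pair lists
    cfg$comparisons <- config$comparisons
  } else {
    # keep only default pairs whose conditions are simulated
    cfg$comparisons <- Filter(function(p) all(p %in% cfg$presets),
                              cfg$comparisons)
  }
  if (is.null(cfg$channel_order) || !length(cfg$channel_order) ||
      !all(cfg$channel_order %in% CHANNEL_ROLES)) {
    bifor_error("invalidConfig",
                "channel_order must name channels among dapi, red, green")
  }
  if (cfg$threshold_quantile <= 0 || cfg$threshold_quantile >= 1) {
    bifor_error("invalidConfig", "threshold_quantile must lie in (0, 1)")
  }
  if (cfg$dilation_radius < 0) {
    bifor_error("invalidConfig", "dilation_radius must be >= 0")
  }
  if (cfg$min_nucleus_size < 0) {
    bifor_error("invalidConfig", "min_nucleus_size must be >= 0")
  }
  if (!cfg$ndim %in% c(2L, 3L)) {
    bifor_error("invalidConfig", "ndim must be 2 or 3")
  }
  if (!cfg$estimator %in% c("strict_max", "quantile")) {
    bifor_error("invalidConfig", "estimator must be strict_max or quantile")
  }
  if (!cfg$test %in% c("mannwhitney", "permutation")) {
    bifor_error("invalidConfig", "test must be mannwhitney or permutation")
  }
  bad <- setdiff(cfg$presets, condition_presets())
  if (length(bad)) {
    bifor_error("invalidConfig",
                sprintf("unknown preset(s): %s", paste(bad, collapse = ", ")))
  }
  structure(cfg, class = "bifor_config")
}

#' Run the full simulate / quantify / compare pipeline
#'
#' Simulates the configured conditions, scores every nucleus, compares the
#' configured condition pairs, and writes into `outdir`: `manifest.csv`,
#' `scores.csv`, `exclusions.csv`, `comparisons.csv`,
#' `replicate_summary.csv`, `config.yaml`, `run.log`, and a summary plot
#' (`scores.pdf`: per-condition score distributions with significance
#' labels). A run is deterministic: the same config (including seed) yields
#' byte-identical score and comparison CSVs.
#'
#' @param config Config list or `bifor_config` (see [validate_config()]).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the scored dataset, score table,
#'   comparison table and `outdir`.
#' @export
run_pipeline <- function(config = list(), outdir) {
  cfg <- validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outdir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat("", file = logf)
  logline("bifor %s | R %s", as.character(utils::packageVersion("bifor")),
          paste(R.version$major, R.version$minor, sep = "."))
  logline("stage: simulate (%d preset(s) x %d x %d nuclei, %dD, seed %d)",
          length(cfg$presets), cfg$n_replicates, cfg$n_nuclei_per_replicate,
          cfg$ndim, cfg$seed)
  dataset <- simulate_experiment(
    presets = cfg$presets,
    n_nuclei_per_replicate = cfg$n_nuclei_per_replicate,
    n_replicates = cfg$n_replicates, seed = cfg$seed,
    outdir = if (cfg$write_images) file.path(outdir, "images") else NULL,
    ndim = cfg$ndim
  )
  write_manifest(dataset$manifest, file.path(outdir, "manifest.csv"))

  logline("stage: quantify (estimator %s, threshold_quantile %g, dilation %g)",
          cfg$estimator, cfg$threshold_quantile, cfg$dilation_radius)
  scored <- score_dataset(dataset,
                          threshold_quantile = cfg$threshold_quantile,
                          dilation_radius = cfg$dilation_radius,
                          min_nucleus_size = cfg$min_nucleus_size,
                          smoothing_sigma = cfg$smoothing_sigma,
                          estimator = cfg$estimator, q = cfg$quantile_q,
                          subtract_median = cfg$subtract_median,
                          exclude_border = cfg$exclude_border)
  utils::write.csv(scored$scores, file.path(outdir, "scores.csv"),
                   row.names = FALSE)
  utils::write.csv(scored$exclusions, file.path(outdir, "exclusions.csv"),
                   row.names = FALSE)
  for (i in seq_len(nrow(scored$exclusions))) {
    logline("excluded %s: %s", scored$exclusions$scene_id[i],
            scored$exclusions$reason[i])
  }

  logline("stage: compare (%s, %d pair(s))", cfg$test,
          length(cfg$comparisons))
  comparisons <- run_condition_matrix(scored, cfg$comparisons,
                                      test = cfg$test, n_perm = cfg$n_perm,
                                      seed = cfg$seed, holm = cfg$holm)
  utils::write.csv(comparisons, file.path(outdir, "comparisons.csv"),
                   row.names = FALSE)
  repsum <- summarize_by_replicate(scored)
  utils::write.csv(repsum, file.path(outdir, "replicate_summary.csv"),
                   row.names = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(outdir, "config.yaml"))
  tryCatch(plot_scores(scored, comparisons,
                       path = file.path(outdir, "scores.pdf")),
           error = function(e) logline("plot skipped: %s",
                                       conditionMessage(e)))
  logline("done: %d nuclei scored, %d excluded",
          nrow(scored$scores), nrow(scored$exclusions))
  invisible(list(dataset = dataset, scores = scored,
                 comparisons = comparisons, outdir = outdir))
}

#' Per-condition score distributions with significance labels
#'
#' Advisory figure-style summary: one box-and-strip panel per condition plus
#' the comparison labels. Written to `path` (PDF) when given, otherwise drawn
#' on the current device.
#'
#' @param scores A `bifor_scores` or score data.frame.
#' @param comparisons Optional comparison table from [run_condition_matrix()].
#' @param path Optional PDF output path.
#' @return Invisibly `NULL`.
#' @export
plot_scores <- function(scores, comparisons = NULL, path = NULL) {
  df <- as_score_df(scores)
  if (!nrow(df)) bifor_error("invalidInput", "no scores to plot")
  if (!is.null(path)) {
    grDevices::pdf(path, width = 8, height = 5)
    on.exit(grDevices::dev.off())
  }
  conds <- unique(df$condition)
  fac <- factor(df$condition, levels = conds)
  graphics::par(mar = c(9, 4, 2, 1))
  graphics::boxplot(value ~ fac, data = df, las = 2, outline = FALSE,
                    ylim = c(0, 1.15), xlab = "", col = "grey90",
                    ylab = "enrichment ratio (locus max / nucleus max)")
  graphics::stripchart(value ~ fac, data = df, vertical = TRUE,
                       method = "jitter", pch = 16, cex = 0.5,
                       col = grDevices::adjustcolor("steelblue", 0.6),
                       add = TRUE)
  if (!is.null(comparisons) && nrow(comparisons)) {
    y <- 1.05
    for (i in seq_len(nrow(comparisons))) {
      ia <- match(comparisons$condition_a[i], conds)
      ib <- match(comparisons$condition_b[i], conds)
      if (is.na(ia) || is.na(ib)) next
      graphics::segments(ia, y, ib, y, col = "grey40")
      graphics::text((ia + ib) / 2, y + 0.03, comparisons$label[i],
                     cex = 0.8)
      y <- y + 0.025
      if (y > 1.14) y <- 1.05
    }
  }
  invisible(NULL)
}
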