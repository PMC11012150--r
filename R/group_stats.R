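# Two-condition comparison of per-nucleus enrichment scores, with the
# three-tier significance labelling convention:
# "***" for p <= 1e-4, "*" for p <= 0.01, "ns" otherwise (no "**" tier).

#' Map a p-value to its significance label
#'
#' @param p A p-value (NA allowed).
#' @return `"***"` if `p <= 1e-4`, `"*"` if `1e-4 < p <= 0.01`, `"ns"` if
#'   `p > 0.01`, `NA` for `NA` input.
#' @export
significance_label <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi <= 1e-4) "***" else if (pi <= 0.01) "*" else "ns"
  }, "")
}

#' Compare enrichment scores between two conditions
#'
#' Two-sided test on per-nucleus scores. `"mannwhitney"` (default) is the
#' normal-approximation Mann-Whitney U, a robust choice for a bounded ratio.
#' `"permutation"` is a seeded difference-of-means permutation test: when the
#' number of distinct group assignments is at most `n_perm` it enumerates all
#' of them exactly; otherwise it draws `n_perm` random shuffles and reports
#' the add-one Monte-Carlo p-value.
#'
#' @param scores_a,scores_b Numeric score vectors (one value per nucleus).
#' @param test `"mannwhitney"` or `"permutation"`.
#' @param n_perm Number of label shuffles for the permutation test.
#' @param seed Seed for the permutation stream.
#' @param condition_a,condition_b Names carried into the result.
#' @return A `bifor_comparison`: condition names, group sizes, `statistic`,
#'   `p_value`, `label`, `test_name`, and `insufficient` (TRUE with `p_value
#'   = NA` when either group has fewer than 2 scores).
#' @export
compare_conditions <- function(scores_a, scores_b,
                               test = c("mannwhitney", "permutation"),
                               n_perm = 10000, seed = 1L,
                               condition_a = "A", condition_b = "B") {
  test <- match.arg(test)
  scores_a <- as.numeric(scores_a)
  scores_b <- as.numeric(scores_b)
  if (!length(scores_a) || !length(scores_b)) {
    bifor_error("invalidInput", "both score vectors must be nonempty")
  }
  n_a <- length(scores_a); n_b <- length(scores_b)
  out <- list(condition_a = condition_a, condition_b = condition_b,
              n_a = n_a, n_b = n_b, statistic = NA_real_,
              p_value = NA_real_, label = NA_character_,
              test_name = test, insufficient = FALSE)
  if (n_a < 2 || n_b < 2) {
    out$insufficient <- TRUE
    return(structure(out, class = "bifor_comparison"))
  }
  if (test == "mannwhitney") {
    ht <- stats::wilcox.test(scores_a, scores_b, exact = FALSE,
                             correct = TRUE)
    out$statistic <- unname(ht$statistic)
    out$p_value <- ht$p.value
  } else {
    pt <- permutation_test(scores_a, scores_b, n_perm = n_perm, seed = seed)
    out$statistic <- pt$statistic
    out$p_value <- pt$p_value
    out$test_name <- pt$test_name
  }
  out$label <- significance_label(out$p_value)
  structure(out, class = "bifor_comparison")
}

# Difference-of-means permutation test; exhaustive when feasible.
permutation_test <- function(a, b, n_perm = 10000, seed = 1L) {
  pool <- c(a, b)
  n <- length(pool); n_a <- length(a)
  obs <- mean(a) - mean(b)
  tol <- 1e-9 * (abs(obs) + stats::sd(pool) + 1e-300)
  n_comb <- choose(n, n_a)
  if (n_comb <= n_perm) {
    idx <- utils::combn(n, n_a)
    tot <- sum(pool)
    stats_perm <- apply(idx, 2, function(j) {
      sa <- sum(pool[j])
      sa / n_a - (tot - sa) / (n - n_a)
    })
    p <- mean(abs(stats_perm) >= abs(obs) - tol)
    name <- "permutation(exhaustive)"
  } else {
    exceed <- with_seed(seed, {
      cnt <- 0L
      for (k in seq_len(n_perm)) {
        j <- sample.int(n, n_a)
        sa <- sum(pool[j])
        stat <- sa / n_a - (sum(pool) - sa) / (n - n_a)
        if (abs(stat) >= abs(obs) - tol) cnt <- cnt + 1L
      }
      cnt
    })
    p <- (1 + exceed) / (1 + n_perm)
    name <- sprintf("permutation(%d shuffles)", n_perm)
  }
  list(statistic = obs, p_value = p, test_name = name)
}

#' @export
print.bifor_comparison <- function(x, ...) {
  if (x$insufficient) {
    cat(sprintf("%s vs %s: insufficient data (n = %d, %d)\n",
                x$condition_a, x$condition_b, x$n_a, x$n_b))
  } else {
    cat(sprintf("%s (n=%d) vs %s (n=%d): %s, statistic %.4g, p = %.3g [%s]\n",
                x$condition_a, x$n_a, x$condition_b, x$n_b, x$test_name,
                x$statistic, x$p_value, x$label))
  }
  invisible(x)
}

#' Per-replicate summary of a score table
#'
#' @param scores A `bifor_scores` or its `scores` data.frame (columns
#'   condition, replicate, value).
#' @return Data.frame with one row per condition x replicate: `n`, `mean`,
#'   `median`.
#' @export
summarize_by_replicate <- function(scores) {
  scores <- as_score_df(scores)
  if (!"replicate" %in% names(scores) || anyNA(scores$replicate)) {
    bifor_error("invalidInput", "score table lacks (complete) replicate ids")
  }
  agg <- stats::aggregate(value ~ condition + replicate, data = scores,
                          FUN = function(v) c(n = length(v), mean = mean(v),
                                              median = stats::median(v)))
  out <- data.frame(condition = agg$condition, replicate = agg$replicate,
                    n = as.integer(agg$value[, "n"]),
                    mean = agg$value[, "mean"],
                    median = agg$value[, "median"],
                    stringsAsFactors = FALSE)
  out[order(out$condition, out$replicate), , drop = FALSE]
}

as_score_df <- function(scores) {
  if (inherits(scores, "bifor_scores")) scores$scores else scores
}

#' Run a matrix of condition comparisons
#'
#' For each requested pair this reports the pooled per-nucleus comparison
#' (all nuclei of a condition, replicates pooled) and, alongside it, a
#' replicate-level comparison: Welch's t-test on the per-replicate mean
#' scores (n = number of replicates). The replicate-level test treats the
#' biological replicate as the experimental unit; with the usual three
#' replicates a rank test on replicate means cannot reach p <= 0.01, so a
#' t-test on means is used there.
#'
#' @param scores A `bifor_scores` or score data.frame.
#' @param comparisons List of 2-element character vectors (condition pairs),
#'   or a 2-column matrix/data.frame.
#' @param test,n_perm,seed Passed to [compare_conditions()] for the pooled
#'   test.
#' @param holm Also report Holm-adjusted pooled p-values and labels.
#' @return Data.frame with one row per pair: condition_a, condition_b, n_a,
#'   n_b, test, statistic, p, label, p_replicate, label_replicate, and
#'   (with `holm`) p_adj, label_adj. No multiplicity adjustment is applied
#'   by default.
#' @export
run_condition_matrix <- function(scores, comparisons,
                                 test = "mannwhitney", n_perm = 10000,
                                 seed = 1L, holm = FALSE) {
  scores <- as_score_df(scores)
  if (is.matrix(comparisons) || is.data.frame(comparisons)) {
    comparisons <- lapply(seq_len(nrow(comparisons)),
                          function(i) as.character(unlist(comparisons[i, 1:2])))
  }
  if (!length(comparisons)) {
    return(data.frame(condition_a = character(), condition_b = character(),
                      n_a = integer(), n_b = integer(), test = character(),
                      statistic = numeric(), p = numeric(),
                      label = character(), p_replicate = numeric(),
                      label_replicate = character(),
                      stringsAsFactors = FALSE))
  }
  known <- unique(scores$condition)
  named <- unique(unlist(comparisons))
  if (length(setdiff(named, known))) {
    bifor_error("unknownCondition",
                sprintf("condition(s) not in score table: %s",
                        paste(setdiff(named, known), collapse = ", ")))
  }
  rows <- lapply(seq_along(comparisons), function(i) {
    pair <- comparisons[[i]]
    a <- scores$value[scores$condition == pair[1]]
    b <- scores$value[scores$condition == pair[2]]
    cmp <- compare_conditions(a, b, test = test, n_perm = n_perm,
                              seed = seed + i - 1L,
                              condition_a = pair[1], condition_b = pair[2])
    rep_p <- replicate_level_p(scores, pair)
    data.frame(condition_a = pair[1], condition_b = pair[2],
               n_a = cmp$n_a, n_b = cmp$n_b, test = cmp$test_name,
               statistic = cmp$statistic, p = cmp$p_value, label = cmp$label,
               p_replicate = rep_p,
               label_replicate = significance_label(rep_p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (holm) {
    out$p_adj <- stats::p.adjust(out$p, method = "holm")
    out$label_adj <- significance_label(out$p_adj)
  }
  out
}

replicate_level_p <- function(scores, pair) {
  if (!"replicate" %in% names(scores) || anyNA(scores$replicate)) {
    return(NA_real_)
  }
  ma <- stats::aggregate(value ~ replicate,
                         data = scores[scores$condition == pair[1], ],
                         FUN = mean)$value
  mb <- stats::aggregate(value ~ replicate,
                         data = scores[scores$condition == pair[2], ],
                         FUN = mean)$value
  if (length(ma) < 2 || length(mb) < 2) return(NA_real_)
  tryCatch(stats::t.test(ma, mb)$p.value, error = function(e) NA_real_)
}
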