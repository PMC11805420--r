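#' @title Baseline resampling and the cross-condition statistical battery
#' @description
#' The Monte Carlo label-resampling baseline ("best guess" predictions drawn
#' with replacement from the training labels and scored against the test
#' labels), Bonferroni-corrected significance calls at the empirical
#' baseline quantile, and the cross-condition tests: paired Wilcoxon between
#' algorithms, Friedman across horizons and mental states, Spearman
#' correlations with class imbalance, and identity-line residuals comparing
#' ordinal and binary scale-normalized balanced error.
#' @name evaluation_stats
NULL

#' Monte Carlo label-resampling baseline distribution
#'
#' Each draw samples `length(test_labels)` labels with replacement from the
#' training labels of the same condition and scores them against the true
#' test labels. The default 12,000 draws resolve the Bonferroni-corrected
#' 4.2e-4 quantile (1/12001 < 4.2e-4); `n_draws = 1000` reproduces the
#' literal published protocol, in which the corrected quantile is
#' resolution-limited and falls back to the extreme order statistic.
#'
#' @param train_labels,test_labels Non-empty label vectors (ordinal for
#'   MAMAE, binary for BAcc).
#' @param metric `"mamae"` or `"bacc"`.
#' @param n_draws Number of Monte Carlo draws.
#' @param seed Integer seed.
#' @return Object of class `baseline_distribution` with `samples`,
#'   `metric`, `n_draws`, `better_direction`.
#' @export
monte_carlo_baseline <- function(train_labels, test_labels,
                                 metric = c("mamae", "bacc"),
                                 n_draws = 12000, seed = 1) {
  metric <- match.arg(metric)
  if (length(train_labels) == 0L || length(test_labels) == 0L)
    stop("empty label set")
  set.seed(seed)
  nt <- length(test_labels)
  draws <- matrix(sample(train_labels, n_draws * nt, replace = TRUE),
                  n_draws, nt)
  if (metric == "mamae") {
    cls <- sort(unique(test_labels))
    per_class <- vapply(cls, function(c0) {
      rowMeans(abs(draws[, test_labels == c0, drop = FALSE] - c0))
    }, numeric(n_draws))
    samples <- rowMeans(per_class)
    direction <- "lower"
  } else {
    if (length(unique(test_labels)) < 2L)
      stop("bacc baseline undefined: single-class test labels")
    tpr <- rowMeans(draws[, test_labels == 1, drop = FALSE] == 1)
    tnr <- rowMeans(draws[, test_labels == 0, drop = FALSE] == 0)
    samples <- (tpr + tnr) / 2
    direction <- "higher"
  }
  structure(list(samples = samples, metric = metric, n_draws = n_draws,
                 better_direction = direction),
            class = "baseline_distribution")
}

# inverse-ECDF (type-1) empirical quantile
quantile_type1 <- function(x, p) {
  xs <- sort(x)
  xs[max(1L, ceiling(p * length(xs)))]
}

#' Bonferroni-corrected significance call against a baseline
#'
#' The corrected alpha is `family_alpha / n_models` (0.05 / 120 = 4.2e-4 for
#' the full grid). The significance threshold is the empirical baseline
#' quantile at the corrected alpha in the better direction (lower tail for
#' error metrics, upper tail for balanced accuracy); a model is significant
#' only if strictly better than the threshold. If the number of draws cannot
#' resolve the corrected alpha (`1/(n_draws+1) > alpha`), the threshold is
#' the extreme order statistic and the call is annotated
#' `resolution_limited`.
#'
#' @param distribution A `baseline_distribution`.
#' @param value The model's test metric.
#' @param n_models Size of the model family for the correction (default
#'   120).
#' @param family_alpha Family-wise alpha (default 0.05).
#' @return List of class `significance_call` with `threshold`,
#'   `is_significant`, `alpha_corrected`, `resolution_limited`.
#' @export
significance_call <- function(distribution, value, n_models = 120,
                              family_alpha = 0.05) {
  stopifnot(inherits(distribution, "baseline_distribution"))
  alpha <- family_alpha / n_models
  limited <- 1 / (distribution$n_draws + 1) > alpha
  if (distribution$better_direction == "lower") {
    threshold <- if (limited) min(distribution$samples)
                 else quantile_type1(distribution$samples, alpha)
    sig <- value < threshold
  } else {
    threshold <- if (limited) max(distribution$samples)
                 else quantile_type1(distribution$samples, 1 - alpha)
    sig <- value > threshold
  }
  structure(list(metric = distribution$metric, value = value,
                 threshold = threshold, is_significant = sig,
                 alpha_corrected = alpha, resolution_limited = limited),
            class = "significance_call")
}

#' Paired Wilcoxon comparison of two algorithms
#'
#' Two-sided Wilcoxon signed-rank test on per-condition test metrics paired
#' by item and horizon within one task (30 pairs on the full grid). Zero
#' differences are dropped, as in the standard treatment; if every pair is
#' tied the statistic is 0 and p = 1.
#'
#' @param metrics Data frame with columns `item`, `horizon`, `algorithm`,
#'   `value`.
#' @return List with `statistic`, `p_value`, `n_pairs`, and the paired
#'   table.
#' @export
compare_algorithms <- function(metrics) {
  algs <- sort(unique(metrics$algorithm))
  if (length(algs) != 2L) stop("exactly two algorithms required")
  wide <- stats::reshape(metrics[, c("item", "horizon", "algorithm", "value")],
                         idvar = c("item", "horizon"),
                         timevar = "algorithm", direction = "wide")
  v1 <- wide[[paste0("value.", algs[1])]]
  v2 <- wide[[paste0("value.", algs[2])]]
  if (anyNA(v1) || anyNA(v2)) stop("unpaired or missing conditions")
  diffs <- v1 - v2
  if (all(diffs == 0))
    return(list(test = "wilcoxon", statistic = 0, p_value = 1,
                n_pairs = length(diffs), pairs = wide))
  wt <- suppressWarnings(stats::wilcox.test(v1, v2, paired = TRUE,
                                            exact = sum(diffs != 0) <= 25,
                                            correct = TRUE))
  list(test = "wilcoxon", statistic = unname(wt$statistic),
       p_value = wt$p.value, n_pairs = length(diffs), pairs = wide)
}

#' Friedman test across horizons or mental states
#'
#' For the horizon analysis, blocks are item x algorithm combinations and
#' treatments the 3 horizons; for the mental-state analysis, blocks are
#' algorithm x horizon combinations and treatments the 10 items.
#'
#' @param metrics Data frame with columns `item`, `horizon`, `algorithm`,
#'   `value` (one task).
#' @param factor `"horizon"` or `"mental_state"`.
#' @return List with `statistic` (Friedman chi-square Q), `p_value`, `df`.
#' @export
friedman_effect <- function(metrics, factor = c("horizon", "mental_state")) {
  factor <- match.arg(factor)
  if (factor == "horizon") {
    treat <- metrics$horizon
    block <- paste(metrics$item, metrics$algorithm)
  } else {
    treat <- metrics$item
    block <- paste(metrics$algorithm, metrics$horizon)
  }
  tab <- table(block, treat)
  if (any(tab != 1L)) stop("incomplete blocks: need one value per block x treatment")
  m <- stats::reshape(data.frame(block = block, treat = treat,
                                 value = metrics$value),
                      idvar = "block", timevar = "treat", direction = "wide")
  mat <- as.matrix(m[, -1, drop = FALSE])
  if (all(apply(mat, 1, function(r) length(unique(r)) == 1L)))
    return(list(test = "friedman", statistic = 0, p_value = 1,
                df = ncol(mat) - 1))
  ft <- stats::friedman.test(mat)
  list(test = "friedman", statistic = unname(ft$statistic),
       p_value = ft$p.value, df = unname(ft$parameter))
}

#' Spearman correlations between imbalance and performance
#'
#' The cross-condition correlations that diagnose metric behaviour under
#' class imbalance: imbalance against MAMAE and MAE on ordinal conditions,
#' imbalance against BAcc and Acc on binary conditions, and the
#' balanced-vs-unbalanced metric pairs.
#'
#' @param results Per-condition data frame with columns `task`,
#'   `imbalance`, and metric columns `mamae`, `mae`, `bacc`, `acc` (NA where
#'   not applicable).
#' @return Data frame with `pair`, `rho`, `p_value`, `n`.
#' @export
imbalance_correlations <- function(results) {
  ord <- results[results$task == "ordinal", , drop = FALSE]
  bin <- results[results$task == "binary", , drop = FALSE]
  pairs <- list(
    c("imbalance", "mamae", "ordinal"), c("imbalance", "mae", "ordinal"),
    c("imbalance", "bacc", "binary"), c("imbalance", "acc", "binary"),
    c("mamae", "mae", "ordinal"), c("bacc", "acc", "binary"))
  out <- do.call(rbind, lapply(pairs, function(p) {
    df <- if (p[3] == "ordinal") ord else bin
    x <- df[[p[1]]]; y <- df[[p[2]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("constant vector in correlation: ", p[1], " vs ", p[2])
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    data.frame(pair = paste(p[1], "vs", p[2]), task = p[3],
               rho = unname(ct$estimate), p_value = ct$p.value,
               n = length(x), stringsAsFactors = FALSE)
  }))
  out
}

#' Identity-line residuals between ordinal and binary error
#'
#' Matches ordinal and binary conditions on item, horizon and algorithm and
#' reports the residuals of the ordinal scale-normalized balanced error
#' against the binary one relative to the identity line; a mean residual
#' near zero indicates equivalent performance on the two tasks.
#'
#' @param results Per-condition data frame with columns `item`, `horizon`,
#'   `algorithm`, `task`, `nbe`.
#' @return List with `mean_residual`, `sd_residual`, `n`, and the matched
#'   `table` of residuals.
#' @export
task_equivalence_residuals <- function(results) {
  ord <- results[results$task == "ordinal",
                 c("item", "horizon", "algorithm", "nbe")]
  bin <- results[results$task == "binary",
                 c("item", "horizon", "algorithm", "nbe")]
  merged <- merge(ord, bin, by = c("item", "horizon", "algorithm"),
                  suffixes = c("_ordinal", "_binary"))
  if (nrow(merged) == 0L || nrow(merged) != nrow(ord) ||
      nrow(merged) != nrow(bin))
    stop("unmatched conditions between tasks")
  merged$residual <- merged$nbe_ordinal - merged$nbe_binary
  list(mean_residual = mean(merged$residual),
       sd_residual = stats::sd(merged$residual),
       n = nrow(merged), table = merged)
}
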