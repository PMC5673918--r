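#' Bin-level copy-number classification metrics
#'
#' Precision, recall and F-measure computed separately for gains and
#' losses. A bin is a gain when its copy number exceeds 2 and a loss when
#' below 2; subclonal predictions count by their copy number. True
#' positives are bins altered in the same direction in both vectors. When
#' the truth contains no positives for a direction, recall (and F) are
#' reported as `NA`.
#'
#' @param pred,truth Integer copy numbers per bin (equal length, valid bins
#'   only).
#' @return Tibble with one row per direction: `direction`, `tp`, `fp`,
#'   `fn`, `precision`, `recall`, `f_measure`.
#' @export
cna_metrics <- function(pred, truth) {
  if (length(pred) != length(truth)) abort("`pred` and `truth` must have equal length")
  one_direction <- function(direction) {
    pp <- if (direction == "gain") pred > 2 else pred < 2
    tp_ <- if (direction == "gain") truth > 2 else truth < 2
    tp <- sum(pp & tp_); fp <- sum(pp & !tp_); fn <- sum(!pp & tp_)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else NA_real_
    tibble::tibble(direction = direction, tp = tp, fp = fp, fn = fn,
                   precision = precision, recall = recall, f_measure = f)
  }
  dplyr::bind_rows(one_direction("gain"), one_direction("loss"))
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact interval for a proportion via Beta quantiles.
#'
#' @param successes Number of successes.
#' @param trials Number of trials (> 0).
#' @param level Confidence level.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
clopper_pearson <- function(successes, trials, level = 0.95) {
  if (trials <= 0) abort("`trials` must be positive")
  if (successes < 0 || successes > trials) abort("`successes` must lie in [0, trials]")
  a <- (1 - level) / 2
  lower <- if (successes == 0) 0 else qbeta(a, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else qbeta(1 - a, successes + 1, trials - successes)
  c(lower = lower, upper = upper)
}

#' Tumor-detection sensitivity and specificity
#'
#' Classifies each sample as tumor-present when its estimated tumor
#' fraction is at or above `threshold`. Sensitivity is computed over
#' samples whose true tumor fraction exceeds `threshold`; specificity over
#' truth-negative samples (true tumor fraction 0). Exact Clopper-Pearson
#' intervals accompany both rates.
#'
#' @param estimated_tf Estimated tumor fractions (or a list of
#'   `ulp_solution` objects).
#' @param truth_tf True/expected tumor fractions, same length.
#' @param threshold Classification threshold.
#' @param level Confidence level for the intervals.
#' @return One-row tibble with sensitivity, specificity, their CI bounds
#'   and the counts behind them.
#' @export
detection_table <- function(estimated_tf, truth_tf, threshold = 0.03, level = 0.95) {
  if (is.list(estimated_tf)) {
    estimated_tf <- purrr::map_dbl(estimated_tf, "tumor_fraction")
  }
  if (length(estimated_tf) != length(truth_tf)) abort("inputs must have equal length")
  detected <- estimated_tf >= threshold
  pos <- truth_tf > threshold
  neg <- truth_tf == 0

  sens_ci <- c(lower = NA_real_, upper = NA_real_)
  sensitivity <- NA_real_
  if (any(pos)) {
    sensitivity <- mean(detected[pos])
    sens_ci <- clopper_pearson(sum(detected[pos]), sum(pos), level)
  }
  specificity <- NA_real_
  spec_ci <- c(lower = NA_real_, upper = NA_real_)
  if (any(neg)) {
    specificity <- mean(!detected[neg])
    spec_ci <- clopper_pearson(sum(!detected[neg]), sum(neg), level)
  }
  tibble::tibble(
    threshold = threshold,
    n_positive = sum(pos), n_negative = sum(neg),
    sensitivity = sensitivity,
    sensitivity_lower = sens_ci[["lower"]], sensitivity_upper = sens_ci[["upper"]],
    specificity = specificity,
    specificity_lower = spec_ci[["lower"]], specificity_upper = spec_ci[["upper"]]
  )
}

#' Tumor-fraction error statistics
#'
#' Elementwise absolute deviations between estimated and expected tumor
#' fractions, summarized by their maximum and median.
#'
#' @param estimated,expected Equal-length numeric vectors.
#' @return One-row tibble with `n`, `max_abs_error`,
#'   `median_abs_deviation`; the per-sample table is in attribute
#'   `per_sample`.
#' @export
tf_error_stats <- function(estimated, expected) {
  if (length(estimated) != length(expected)) abort("inputs must have equal length")
  dev <- abs(estimated - expected)
  out <- tibble::tibble(
    n = length(dev),
    max_abs_error = max(dev),
    median_abs_deviation = median(dev)
  )
  attr(out, "per_sample") <- tibble::tibble(
    expected = expected, estimated = estimated, deviation = dev
  )
  out
}
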