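#' Spearman's rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive average
#' ranks). A constant vector on either side leaves the ranking undefined and
#' raises an error rather than returning a silent 0.
#'
#' @param pred,truth Numeric vectors of equal length >= 2.
#' @return The rank correlation in `[-1, 1]`.
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)) # 0.8
#' @export
spearman_rho <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) < 2) {
    abort_ntaug("`pred` and `truth` must have equal length >= 2.", "config_error")
  }
  if (length(unique(pred)) < 2 || length(unique(truth)) < 2) {
    abort_ntaug("Spearman's rho is undefined for a constant vector.",
                "undefined_metric")
  }
  unname(stats::cor(pred, truth, method = "spearman"))
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the standard
#' convention that any zero factor in the denominator (e.g. single-class
#' predictions) yields 0.
#'
#' @param pred,truth Binary (0/1) vectors of equal length >= 1.
#' @return The coefficient in `[-1, 1]`.
#' @export
mcc <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) < 1) {
    abort_ntaug("`pred` and `truth` must have equal positive length.", "config_error")
  }
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1))) {
    abort_ntaug("MCC inputs must be binary 0/1 vectors.", "config_error")
  }
  tp <- sum(pred == 1 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  denom <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (denom == 0) return(0)
  ((tp * tn) - (fp * fn)) / denom
}

#' Aggregate metric values over test replicates and seeds
#'
#' Values are first averaged over the replicates within each seed, then
#' summarized over seeds: mean, sd, and (for >= 2 seeds) the normal 95%
#' confidence interval `mean +/- 1.96 * sd / sqrt(n_seeds)`.
#'
#' @param values Numeric matrix, seeds in rows and replicates in columns (or
#'   a list of equal-length per-seed numeric vectors).
#' @param metric Metric name recorded in the result.
#' @return An object of class `nta_metric_result`: list with `metric`,
#'   `per_seed` (replicate means), `mean`, `sd`, `n_seeds`, `ci95` (`NULL`
#'   for a single seed).
#' @export
aggregate_metrics <- function(values, metric = c("spearman_rho", "mcc")) {
  metric <- match.arg(metric)
  if (is.list(values)) {
    if (length(unique(lengths(values))) != 1) {
      abort_ntaug("All seeds must have the same number of replicates.",
                  "aggregation_error")
    }
    values <- do.call(rbind, values)
  }
  if (!is.matrix(values)) values <- matrix(values, nrow = 1)
  per_seed <- rowMeans(values)
  n_seeds <- length(per_seed)
  m <- mean(per_seed)
  s <- if (n_seeds > 1) stats::sd(per_seed) else 0
  ci <- if (n_seeds > 1) {
    c(m - 1.96 * s / sqrt(n_seeds), m + 1.96 * s / sqrt(n_seeds))
  } else {
    NULL
  }
  structure(
    list(metric = metric, per_seed = per_seed, mean = m, sd = s,
         n_seeds = n_seeds, ci95 = ci),
    class = "nta_metric_result"
  )
}

#' @export
print.nta_metric_result <- function(x, ...) {
  cat(sprintf("<%s> mean %.4f +/- %.4f over %d seed(s)\n",
              x$metric, x$mean, x$sd, x$n_seeds))
  invisible(x)
}

#' Compare baseline and augmented runs
#'
#' Tabulates mean +/- sd for each condition against the baseline and flags
#' the delta of each augmented condition.
#'
#' @param baseline An `nta_metric_result` for the baseline.
#' @param conditions Named list of `nta_metric_result`s for augmented runs
#'   (may be empty).
#' @return A tibble with columns `condition`, `mean`, `sd`, `n_seeds`,
#'   `delta_vs_baseline`.
#' @export
compare_runs <- function(baseline, conditions = list()) {
  stopifnot(inherits(baseline, "nta_metric_result"))
  for (r in conditions) {
    if (!inherits(r, "nta_metric_result") || r$metric != baseline$metric) {
      abort_ntaug("All conditions must share the baseline's metric.",
                  "config_error")
    }
  }
  rows <- c(list(baseline = baseline), conditions)
  tibble::tibble(
    condition = names(rows),
    metric = vapply(rows, `[[`, character(1), "metric"),
    mean = vapply(rows, `[[`, numeric(1), "mean"),
    sd = vapply(rows, `[[`, numeric(1), "sd"),
    n_seeds = vapply(rows, function(r) as.integer(r$n_seeds), integer(1)),
    delta_vs_baseline = vapply(rows, function(r) r$mean - baseline$mean, numeric(1))
  )
}
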