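# Base-resolution metrics (IOU, per-sequence Pearson), Welch's t-test, and
# peak-count stratification.

#' Intersection over union of predicted and labeled base sets
#'
#' Predictions are binarized at `threshold`; IOU is computed over all bases
#' pooled across the evaluated set. Defined as 1 when both sets are empty.
#'
#' @param pred Numeric vector of predicted probabilities (pool sequences by
#'   concatenation).
#' @param labels Binary labels of the same length.
#' @param threshold Binarization threshold (default 0.5).
#' @return IOU in `[0, 1]`.
#' @export
iou <- function(pred, labels, threshold = 0.5) {
  if (length(pred) != length(labels)) stop("pred/label length mismatch")
  P <- pred >= threshold
  L <- labels != 0
  union <- sum(P | L)
  if (union == 0L) return(1)
  sum(P & L) / union
}

#' Per-sequence Pearson correlation between predicted and observed signal
#'
#' Computed per sequence and averaged; sequences with zero variance in
#' either vector are skipped and counted.
#'
#' @param pred Matrix (sequences x positions) or a single numeric vector.
#' @param observed Same shape as `pred`.
#' @return List with `score` (mean over scored sequences), `per_sequence`,
#'   and `n_skipped`.
#' @export
pearson_score <- function(pred, observed) {
  if (is.null(dim(pred))) {
    pred <- matrix(pred, nrow = 1)
    observed <- matrix(observed, nrow = 1)
  }
  if (!all(dim(pred) == dim(observed))) stop("shape mismatch")
  if (ncol(pred) < 2L) stop("need at least 2 bases per sequence")
  per <- vapply(seq_len(nrow(pred)), function(i) {
    if (stats::sd(pred[i, ]) == 0 || stats::sd(observed[i, ]) == 0) NA_real_
    else stats::cor(pred[i, ], observed[i, ])
  }, numeric(1))
  list(score = mean(per, na.rm = TRUE), per_sequence = per,
       n_skipped = sum(is.na(per)))
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value.
#'
#' @param a,b Numeric vectors (each with at least 2 values).
#' @param alternative Passed to the underlying test (default two-sided).
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b, alternative = "two.sided") {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  ht <- stats::t.test(a, b, var.equal = FALSE, alternative = alternative)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Stratify datasets by peak count
#'
#' low: <= 10000 peaks; middle: 10001..20000; high: > 20000.
#'
#' @param peak_counts Integer vector of peak counts.
#' @return Factor with levels `low`, `middle`, `high`.
#' @export
stratify_by_peaks <- function(peak_counts) {
  cut(peak_counts, breaks = c(-Inf, 10000, 20000, Inf),
      labels = c("low", "middle", "high"))
}

#' Score a fitted model on held-out examples
#'
#' Binary task: pooled IOU over the test bases (plus per-sequence IOUs);
#' signal task: mean per-sequence Pearson correlation.
#'
#' @param model A `quanv_model`.
#' @param dataset The `chip_dataset` it was trained on.
#' @param idx Example indices to score (typically the fit's test split).
#' @param threshold IOU binarization threshold (binary task).
#' @return List with `metric` name, `value`, and `per_sequence`.
#' @export
evaluate_model <- function(model, dataset, idx, threshold = 0.5) {
  preds <- predict(model, lapply(dataset$examples[idx], `[[`, "onehot"))
  labels <- do.call(rbind, lapply(dataset$examples[idx], `[[`, "label"))
  if (dataset$task == "binary") {
    pooled <- iou(as.vector(t(preds)), as.vector(t(labels)), threshold)
    per <- vapply(seq_len(nrow(preds)), function(i) {
      iou(preds[i, ], labels[i, ], threshold)
    }, numeric(1))
    list(metric = "iou", value = pooled, per_sequence = per)
  } else {
    ps <- pearson_score(preds, labels)
    list(metric = "pearson", value = ps$score, per_sequence = ps$per_sequence)
  }
}
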