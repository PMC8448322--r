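# Genome-level matching rules and metrics.
#
# A prediction matches a truth element iff it lies within `margin` bp of
# the element's anchor position. True positives are counted at the region
# level (a truth element with one or more matching predictions counts
# once); false positives at the prediction level (a prediction matching
# no element). The asymmetry is deliberate: it is what makes
# FP-per-correct = FP/TP meaningful at genome scale.

#' Match predictions against truth elements
#'
#' @param preds prediction data frame with columns `chrom` and `pos`.
#' @param truth an [annotation_set] (or data frame with `chrom`, `pos`).
#' @param margin matching margin in bp (default 500).
#' @return list with counts `TP`, `FP`, `FN`, logical vector
#'   `pred_matched` (per prediction) and `truth_matched` (per truth
#'   element).
#' @export
match_predictions <- function(preds, truth, margin = 500L) {
  if (margin < 0L) stop("margin must be >= 0")
  pred_matched <- if (nrow(preds)) {
    min_truth_distance(preds$chrom, preds$pos, truth) <= margin
  } else logical(0)
  truth_matched <- if (nrow(truth)) {
    min_truth_distance(truth$chrom, truth$pos, preds) <= margin
  } else logical(0)
  TP <- sum(truth_matched)
  list(TP = TP, FP = sum(!pred_matched), FN = nrow(truth) - TP,
       pred_matched = pred_matched, truth_matched = truth_matched)
}

#' Compute genome-level evaluation metrics
#'
#' Recall = TP/(TP+FN), precision = TP/(TP+FP), F1 their harmonic mean,
#' FP-per-correct = FP/TP, and FP per megabase = 1e6 * FP / genome_span.
#' Degenerate denominators yield 0 for recall/precision/F1;
#' FP-per-correct is `Inf` when TP = 0 and FP > 0.
#'
#' @param TP,FP,FN non-negative counts.
#' @param genome_span evaluated genome span in bp (> 0).
#' @param margin matching margin recorded in the report.
#' @return list of class `eval_report`.
#' @export
compute_metrics <- function(TP, FP, FN, genome_span, margin = 500L) {
  if (genome_span <= 0) stop("genome_span must be > 0")
  if (any(c(TP, FP, FN) < 0)) stop("counts must be >= 0")
  recall <- if (TP + FN > 0) TP / (TP + FN) else 0
  precision <- if (TP + FP > 0) TP / (TP + FP) else 0
  f1 <- if (recall + precision > 0) {
    2 * recall * precision / (recall + precision)
  } else 0
  fp_per_correct <- if (TP > 0) FP / TP else if (FP > 0) Inf else 0
  structure(list(TP = TP, FP = FP, FN = FN, recall = recall,
                 precision = precision, f1 = f1,
                 fp_per_correct = fp_per_correct,
                 fp_per_mb = 1e6 * FP / genome_span,
                 margin = margin, genome_span = genome_span),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "eval: TP %d FP %d FN %d | recall %.3f precision %.3f F1 %.3f | FP/correct %.3f FP/Mb %.2f (margin %d bp over %d bp)\n",
    x$TP, x$FP, x$FN, x$recall, x$precision, x$f1, x$fp_per_correct,
    x$fp_per_mb, x$margin, x$genome_span))
  invisible(x)
}

#' Evaluate predictions against a truth set
#'
#' Convenience wrapper: [match_predictions()] + [compute_metrics()].
#'
#' @inheritParams match_predictions
#' @inheritParams compute_metrics
#' @return an `eval_report`.
#' @export
evaluate_predictions <- function(preds, truth, genome_span,
                                 margin = 500L) {
  m <- match_predictions(preds, truth, margin)
  compute_metrics(m$TP, m$FP, m$FN, genome_span, margin)
}

#' Ratio of mean signals (fold increase)
#'
#' @param low,high mean signal in the low- and high-scoring groups;
#'   `low` must be positive.
#' @return `high / low`.
#' @export
fold_increase <- function(low, high) {
  if (any(low <= 0)) stop("low-group mean must be > 0")
  high / low
}

#' Recall / FP-per-Mb trade-off across decision thresholds
#'
#' Candidates retained from a scan at `pred_threshold = 0` are distance-
#' filtered once, then re-thresholded and re-matched at each requested
#' threshold without rescanning, so recall is non-increasing in the
#' threshold by construction.
#'
#' @param candidates data frame with `chrom`, `pos`, `score`.
#' @param truth an [annotation_set].
#' @param thresholds numeric vector of decision thresholds (sorted
#'   internally).
#' @param genome_span evaluated span in bp.
#' @param margin matching margin in bp.
#' @param min_separation distance-filter radius in bp.
#' @return data frame with columns `threshold`, `recall`, `precision`,
#'   `fp_per_mb`.
#' @export
recall_at_threshold_curve <- function(candidates, truth, thresholds,
                                      genome_span, margin = 500L,
                                      min_separation = 500L) {
  thresholds <- sort(thresholds)
  filtered <- do.call(rbind, lapply(split(candidates, candidates$chrom),
                                    function(cc) {
    distance_filter(cc, min_separation)
  }))
  rows <- lapply(thresholds, function(t) {
    preds <- filtered[filtered$score >= t, , drop = FALSE]
    rep <- evaluate_predictions(preds, truth, genome_span, margin)
    data.frame(threshold = t, recall = rep$recall,
               precision = rep$precision, fp_per_mb = rep$fp_per_mb)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
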