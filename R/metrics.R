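#' Confusion-matrix skill statistics
#'
#' Computes sensitivity, specificity, TSS, Cohen's kappa and the critical
#' success index (threat score) from a 2x2 confusion table.
#'
#' TSS = sensitivity + specificity - 1; kappa is chance-corrected
#' agreement; CSI = TP / (TP + FP + FN) ignores true negatives.
#'
#' @param tp,fp,fn,tn non-negative confusion counts; at least one actual
#'   positive (`tp + fn`) and one actual negative (`fp + tn`) required.
#' @return named list: `sensitivity`, `specificity`, `TSS`, `kappa`,
#'   `CSI`.
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  if (tp + fn == 0 || fp + tn == 0) stop("degenerate confusion table")
  n <- tp + fp + fn + tn
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  p_o <- (tp + tn) / n
  p_e <- ((tp + fn) * (tp + fp) + (fp + tn) * (fn + tn)) / n^2
  kappa <- if (p_e == 1) 0 else (p_o - p_e) / (1 - p_e)
  csi <- if (tp + fp + fn == 0) 0 else tp / (tp + fp + fn)
  list(sensitivity = sens, specificity = spec,
       TSS = sens + spec - 1, kappa = kappa, CSI = csi)
}

#' Rank-based AUC (Mann-Whitney with midrank ties)
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1); both classes must be present.
#' @return AUC in `[0, 1]`; invariant under strictly monotone transforms
#'   of `scores`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both label classes must be present")
  r <- rank(scores)  # midranks for ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold maximizing TSS
#'
#' Scans every midpoint between consecutive sorted unique scores (a cell
#' is predicted present iff its score exceeds the threshold) and returns
#' the threshold with maximal TSS, ties broken toward the smaller
#' threshold. Equivalent to an exhaustive search over all achievable
#' binarizations.
#'
#' @param scores,labels as in [auc_score()].
#' @return list with `threshold` and `metrics` (an `eval_metrics`
#'   object, see [evaluate_predictions()]).
#' @export
optimize_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L) {
    stop("both label classes must be present")
  }
  u <- sort(unique(scores))
  cand <- if (length(u) >= 2L) (u[-1L] + u[-length(u)]) / 2 else u
  best <- NULL
  for (th in cand) {
    pred <- as.integer(scores > th)
    tp <- sum(pred == 1L & labels == 1L); fp <- sum(pred == 1L & labels == 0L)
    fn <- sum(pred == 0L & labels == 1L); tn <- sum(pred == 0L & labels == 0L)
    m <- confusion_metrics(tp, fp, fn, tn)
    if (is.null(best) || m$TSS > best$metrics$TSS + 1e-12) {
      best <- list(threshold = th,
                   metrics = c(m, list(tp = tp, fp = fp, fn = fn, tn = tn)))
    }
  }
  best
}

#' Evaluate probabilistic predictions against binary labels
#'
#' Bundles rank AUC with the TSS-optimal binarization into one record
#' carrying the four skill metrics used for model screening.
#'
#' @param scores,labels as in [auc_score()].
#' @return object of class `eval_metrics`: `K_TSS`, `K_ROC`, `K_KAPPA`,
#'   `K_CSI`, `threshold`, and confusion counts `tp`, `fp`, `fn`, `tn`.
#' @export
evaluate_predictions <- function(scores, labels) {
  opt <- optimize_threshold(scores, labels)
  m <- opt$metrics
  structure(list(K_TSS = m$TSS, K_ROC = auc_score(scores, labels),
                 K_KAPPA = m$kappa, K_CSI = m$CSI,
                 sensitivity = m$sensitivity, specificity = m$specificity,
                 threshold = opt$threshold,
                 tp = m$tp, fp = m$fp, fn = m$fn, tn = m$tn),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("eval_metrics: TSS %.3f | AUC %.3f | kappa %.3f | CSI %.3f (thr %.3f)\n",
              x$K_TSS, x$K_ROC, x$K_KAPPA, x$K_CSI, x$threshold))
  invisible(x)
}

#' Conditional weights of the composite model score
#'
#' Each metric contributes with weight 0.5 when it exceeds its quality
#' threshold (CSI 0.3, kappa 0.4, AUC 0.9, TSS 0.7) and with weight 0.3
#' otherwise; the sum is divided by the number of metrics.
#'
#' @return list with `thresholds`, `above`, `below`, `divisor`.
#' @export
gamma_weights <- function() {
  list(thresholds = c(CSI = 0.3, KAPPA = 0.4, ROC = 0.9, TSS = 0.7),
       above = 0.5, below = 0.3, divisor = 4)
}

#' Composite model score (conditional-weight mean of four metrics)
#'
#' gamma = (1/4) * sum over m in {CSI, KAPPA, ROC, TSS} of
#' `K_m * 0.5` if `K_m > threshold_m`, else `K_m * 0.3`.
#' For metrics in `[0, 1]` the score lies in `[0, 0.5]` and is monotone
#' non-decreasing in every metric.
#'
#' @param metrics an `eval_metrics` object, or a named vector/list with
#'   `K_CSI`, `K_KAPPA`, `K_ROC`, `K_TSS` (bare names `CSI`, ... also
#'   accepted).
#' @param weights a [gamma_weights()] configuration.
#' @return the scalar composite score.
#' @export
gamma_score <- function(metrics, weights = gamma_weights()) {
  metrics <- as.list(metrics)
  get_m <- function(nm) {
    v <- metrics[[paste0("K_", nm)]]
    if (is.null(v)) v <- metrics[[nm]]
    if (is.null(v) || is.na(v)) stop(sprintf("metric '%s' missing", nm))
    as.numeric(v)
  }
  total <- 0
  for (nm in names(weights$thresholds)) {
    k <- get_m(nm)
    w <- if (k > weights$thresholds[[nm]]) weights$above else weights$below
    total <- total + k * w
  }
  total / weights$divisor
}
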