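#' ROC curve for P2/P1 cut-offs against intracranial hypertension
#'
#' Scans thresholds over all distinct score values (classification positive
#' when score >= threshold), computing sensitivity and specificity at each,
#' and integrates the AUC by the trapezoidal rule over the resulting
#' (1 - specificity, sensitivity) points. With the trapezoid over tied
#' scores this equals the Mann-Whitney probability with half credit for
#' ties — see [auc_mann_whitney()] and [auc_equivalence_check()].
#'
#' @param scores numeric scores (typically the noninvasive minute-level
#'   P2/P1 ratio).
#' @param labels logical/0-1 outcome (typically invasive mean ICP of the same
#'   minute > 20 mmHg); both classes must be present.
#' @return Object of class `roc_result`: `auc`, `threshold_table` (data.frame
#'   `threshold`, `sensitivity`, `specificity` in decreasing threshold
#'   order), `optimal_threshold` (Youden's J; highest threshold on ties),
#'   `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  z <- check_scores(scores, labels)
  scores <- z$scores; labels <- z$labels
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  # counts per distinct threshold value, accumulated in descending order
  tp <- cumsum(vapply(thr, function(v) sum(labels & scores == v), numeric(1)))
  fp <- cumsum(vapply(thr, function(v) sum(!labels & scores == v), numeric(1)))
  sens <- tp / n_pos
  spec <- 1 - fp / n_neg
  tab <- data.frame(threshold = thr, sensitivity = sens, specificity = spec)
  tpr <- c(0, sens)
  fpr <- c(0, 1 - spec)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  j <- sens + spec - 1
  structure(list(auc = auc, threshold_table = tab,
                 optimal_threshold = thr[which.max(j)],
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%d positive / %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  i <- which(x$threshold_table$threshold == x$optimal_threshold)
  cat(sprintf(
    "  Youden-optimal cut-off >= %.3g: sensitivity %.2f, specificity %.2f\n",
    x$optimal_threshold, x$threshold_table$sensitivity[i],
    x$threshold_table$specificity[i]))
  invisible(x)
}

#' Sensitivity and specificity at one cut-off
#'
#' @inheritParams roc_curve
#' @param threshold cut-off; positive call when score >= threshold.
#' @return List `sensitivity`, `specificity`.
#' @export
threshold_metrics <- function(scores, labels, threshold) {
  z <- check_scores(scores, labels)
  pos_call <- z$scores >= threshold
  list(sensitivity = sum(pos_call & z$labels) / sum(z$labels),
       specificity = sum(!pos_call & !z$labels) / sum(!z$labels))
}

#' AUC by brute-force Mann-Whitney pair counting
#'
#' Enumerates every positive-negative pair, crediting 1 when the positive
#' scores higher and 1/2 on ties. Serves as the independent reference for
#' the trapezoidal integration in [roc_curve()].
#'
#' @inheritParams roc_curve
#' @return The Mann-Whitney AUC.
#' @export
auc_mann_whitney <- function(scores, labels) {
  z <- check_scores(scores, labels)
  sp <- z$scores[z$labels]
  sn <- z$scores[!z$labels]
  total <- 0
  for (v in sp) {
    total <- total + sum(v > sn) + 0.5 * sum(v == sn)
  }
  total / (length(sp) * length(sn))
}

#' Check trapezoidal and pair-counting AUC agree
#'
#' @inheritParams roc_curve
#' @param tol equality tolerance (default 1e-12).
#' @return TRUE iff the two AUC computations agree within `tol`.
#' @export
auc_equivalence_check <- function(scores, labels, tol = 1e-12) {
  abs(roc_curve(scores, labels)$auc - auc_mann_whitney(scores, labels)) < tol
}

#' Bootstrap confidence interval for the AUC
#'
#' Percentile bootstrap over observations, deterministic given `seed`. The
#' study this layer mirrors reports ROC CIs without stating their method;
#' this stratified-resampling CI is provided as an extension under the same
#' seed discipline as the rest of the package.
#'
#' @inheritParams roc_curve
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @return List `auc`, `ci_low`, `ci_high`, `n_boot`, `seed`.
#' @export
roc_auc_ci <- function(scores, labels, n_boot = 2000L, seed = 1L) {
  z <- check_scores(scores, labels)
  auc <- roc_curve(z$scores, z$labels)$auc
  n <- length(z$scores)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (all(z$labels[i]) || !any(z$labels[i])) return(NA_real_)
      roc_curve(z$scores[i], z$labels[i])$auc
    }, numeric(1))
  })
  ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(auc = auc, ci_low = ci[1], ci_high = ci[2],
       n_boot = as.integer(n_boot), seed = as.integer(seed))
}

check_scores <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have equal length", call. = FALSE)
  }
  labels <- as.logical(labels)
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (!any(labels) || all(labels)) {
    stop("degenerate labels: both classes must be present", call. = FALSE)
  }
  list(scores = scores, labels = labels)
}
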