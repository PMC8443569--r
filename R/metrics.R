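#' Rank-based ROC AUC
#'
#' Area under the ROC curve computed from the rank statistic (equivalent to
#' the probability that a random positive scores above a random negative, with
#' ties counted one half).
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores numeric scores, same length.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(labels, scores) {
  check_two_class(labels, scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-function integration over the ranked predictions (average precision):
#' `sum over ranked positives of (delta recall) * precision`, with tied scores
#' grouped so the result does not depend on the order within ties.
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores numeric scores, same length.
#' @return AUPR in (0, 1].
#' @export
pr_auc <- function(labels, scores) {
  check_two_class(labels, scores)
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  sc <- scores[o]
  grp <- cumsum(!duplicated(sc))            # 1,1,2,... per tied-score block
  tp_g <- tapply(lab, grp, sum)
  n_g <- tapply(lab, grp, length)
  tp <- cumsum(tp_g)
  npred <- cumsum(n_g)
  precision <- tp / npred
  recall <- tp / sum(labels == 1)
  d_recall <- diff(c(0, recall))
  sum(d_recall * precision)
}

check_two_class <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    stop("`labels` and `scores` must have the same length", call. = FALSE)
  }
  if (!any(labels == 1) || !any(labels == 0)) {
    stop("metric undefined: both classes must be present", call. = FALSE)
  }
  invisible(TRUE)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the
#' conventional value 0 when any factor of the denominator is zero.
#'
#' @param labels 0/1 truth vector.
#' @param preds 0/1 prediction vector, same length.
#' @return MCC in [-1, 1].
#' @export
mcc_score <- function(labels, preds) {
  if (length(labels) != length(preds)) {
    stop("`labels` and `preds` must have the same length", call. = FALSE)
  }
  tp <- as.numeric(sum(labels == 1 & preds == 1))
  tn <- as.numeric(sum(labels == 0 & preds == 0))
  fp <- as.numeric(sum(labels == 0 & preds == 1))
  fn <- as.numeric(sum(labels == 1 & preds == 0))
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Per-pair residue AUC
#'
#' One ROC AUC per pair over its unmasked peptide positions. Pairs without
#' both a positive and a negative unmasked residue are skipped and counted as
#' ineligible.
#'
#' @param labels_list list of 0/1 residue-label vectors (true length each).
#' @param probs_list list of predicted probability vectors, same lengths.
#' @return list with `per_pair` (numeric vector of AUCs), `mean`, `n_eligible`
#'   and `n_skipped`.
#' @export
per_pair_residue_auc <- function(labels_list, probs_list) {
  stopifnot(length(labels_list) == length(probs_list))
  aucs <- numeric(0)
  skipped <- 0L
  for (i in seq_along(labels_list)) {
    lab <- labels_list[[i]]
    if (is.null(lab) || !any(lab == 1) || !any(lab == 0)) {
      skipped <- skipped + 1L
      next
    }
    aucs <- c(aucs, roc_auc(lab, probs_list[[i]]))
  }
  if (length(aucs) == 0) {
    stop("no pair is eligible for residue AUC (need both residue classes)",
         call. = FALSE)
  }
  list(per_pair = aucs, mean = mean(aucs), n_eligible = length(aucs),
       n_skipped = skipped)
}

#' Evaluate model predictions on a labelled pair table
#'
#' Computes the pair-level AUC and AUPR, the per-pair residue AUCs with their
#' mean, and the residue-level MCC at the 0.5 threshold. MCC is pooled over
#' all unmasked residues of all labelled pairs by default; `mcc_per_pair`
#' averages per-pair MCCs instead.
#'
#' @param truth a [pair_table()] with labels (and binding vectors where
#'   available).
#' @param predictions output of [predict.pepnet()] aligned row-by-row with
#'   `truth$pairs`.
#' @param mcc_per_pair average per-pair residue MCC instead of pooling.
#' @return list of class `pepnet_metrics`: `pair_auc`, `pair_aupr`,
#'   `residue_auc_per_pair`, `mean_residue_auc`, `mcc`, `n_pairs_scored`.
#' @export
evaluate_predictions <- function(truth, predictions, mcc_per_pair = FALSE) {
  stopifnot(inherits(truth, "pair_table"))
  labels <- truth$pairs$label
  ok <- !is.na(predictions$prob)
  pair_auc <- roc_auc(labels[ok], predictions$prob[ok])
  pair_aupr <- pr_auc(labels[ok], predictions$prob[ok])

  has_bind <- which(!is.na(truth$pairs$bind) & ok)
  res <- NULL
  mcc <- NA_real_
  if (length(has_bind) > 0) {
    lab_list <- lapply(has_bind, function(i) parse_bind(truth$pairs$bind[i]))
    prob_list <- lapply(has_bind, function(i) predictions$residue_scores[[i]])
    res <- tryCatch(per_pair_residue_auc(lab_list, prob_list),
                    error = function(e) NULL)
    if (mcc_per_pair) {
      vals <- mapply(function(l, p) mcc_score(l, classify_residue(p)),
                     lab_list, prob_list)
      mcc <- mean(vals)
    } else {
      mcc <- mcc_score(unlist(lab_list),
                       classify_residue(unlist(prob_list)))
    }
  }
  structure(list(
    pair_auc = pair_auc,
    pair_aupr = pair_aupr,
    residue_auc_per_pair = res$per_pair,
    mean_residue_auc = res$mean,
    mcc = mcc,
    n_pairs_scored = sum(ok)
  ), class = "pepnet_metrics")
}

#' @export
print.pepnet_metrics <- function(x, ...) {
  cat("pepnet evaluation\n")
  cat(sprintf("  pairs scored:      %d\n", x$n_pairs_scored))
  cat(sprintf("  pair AUC:          %.4f\n", x$pair_auc))
  cat(sprintf("  pair AUPR:         %.4f\n", x$pair_aupr))
  if (!is.null(x$mean_residue_auc)) {
    cat(sprintf("  mean residue AUC:  %.4f (over %d eligible pairs)\n",
                x$mean_residue_auc, length(x$residue_auc_per_pair)))
  }
  if (!is.na(x$mcc)) cat(sprintf("  residue MCC:       %.4f\n", x$mcc))
  invisible(x)
}
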