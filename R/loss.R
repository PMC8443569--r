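#' Binary cross-entropy loss for pair classification
#'
#' `-(1/N) * sum(y * log(y') + (1 - y) * log(1 - y'))` over the N pairs, with
#' probabilities clipped to `[eps, 1 - eps]` before the logs.
#'
#' @param labels 0/1 vector.
#' @param probs predicted probabilities, same length.
#' @param eps clipping constant (default 1e-7).
#' @return non-negative scalar.
#' @examples
#' pair_loss(1, 0.5)  # log(2)
#' @export
pair_loss <- function(labels, probs, eps = 1e-7) {
  if (length(labels) != length(probs)) {
    stop("`labels` and `probs` must have the same length", call. = FALSE)
  }
  p <- clip_prob(probs, eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Masked cross-entropy loss for residue binding prediction
#'
#' Per sample, the cross-entropy over its real (unmasked) peptide positions is
#' averaged over the `M_i = sum_k m_ik` unmasked positions; the per-sample
#' means are then averaged over the N samples. Positions with mask 0
#' contribute exactly zero, so arbitrary values at padded positions cannot
#' change the loss. A sample with no unmasked position (e.g. a pair without
#' residue labels) contributes zero.
#'
#' @param labels N x L 0/1 matrix of binding labels.
#' @param probs N x L matrix of predicted probabilities.
#' @param masks N x L 0/1 matrix (1 = position enters the loss).
#' @param eps clipping constant.
#' @return non-negative scalar.
#' @export
residue_loss <- function(labels, probs, masks, eps = 1e-7) {
  if (!all(dim(labels) == dim(probs)) || !all(dim(labels) == dim(masks))) {
    stop("`labels`, `probs` and `masks` must have identical dimensions",
         call. = FALSE)
  }
  p <- clip_prob(probs, eps)
  ce <- -(labels * log(p) + (1 - labels) * log(1 - p)) * masks
  Mi <- rowSums(masks)
  per_sample <- ifelse(Mi > 0, rowSums(ce) / pmax(Mi, 1), 0)
  mean(per_sample)
}

#' Combined dual-task loss
#'
#' `loss_total = loss_pair + lambda * loss_pep`.
#'
#' @param loss_pair pair-classification loss.
#' @param loss_pep residue-classification loss.
#' @param lambda non-negative weight of the residue task.
#' @return scalar.
#' @export
total_loss <- function(loss_pair, loss_pep, lambda) {
  if (lambda < 0) stop("`lambda` must be non-negative", call. = FALSE)
  loss_pair + lambda * loss_pep
}

#' Threshold a probability into a binary call
#'
#' Both tasks use the same decision rule: a score of at least 0.5 is called
#' positive (the boundary itself is positive).
#'
#' @param prob probability vector in [0, 1].
#' @return integer 0/1 vector.
#' @export
classify_pair <- function(prob) {
  if (any(prob < 0 | prob > 1)) stop("probabilities must be in [0, 1]", call. = FALSE)
  as.integer(prob >= 0.5)
}

#' @rdname classify_pair
#' @export
classify_residue <- classify_pair
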