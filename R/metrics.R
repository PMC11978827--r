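# Evaluation primitives: cross-modal retrieval accuracy, voxel-wise Pearson
# correlation, and the detection/segmentation metric primitives (IoU, mean
# IoU, average precision from precision/recall points).

#' Top-k cross-modal retrieval accuracy
#'
#' Fraction of samples whose true partner `q_i` is among the `k` fMRI
#' features most similar to `p_i` (dot-product similarity, optionally on
#' unit-normalized rows). Ties are broken in favour of the lower index.
#'
#' @param P `n x d` query features.
#' @param Q `n x d` candidate features, row `i` the true partner of `P[i, ]`.
#' @param k candidates considered, `1 <= k <= n`.
#' @param normalize unit-normalize rows first (default TRUE, i.e. cosine).
#' @return fraction in `[0, 1]`.
#' @export
retrieval_accuracy <- function(P, Q, k = 1, normalize = TRUE) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q)))
    nf_shape_error("P and Q must have identical shapes")
  n <- nrow(P)
  if (k < 1 || k > n)
    nf_config_error("k must satisfy 1 <= k <= n (k=%d, n=%d)", k, n)
  if (normalize) { P <- l2_normalize_rows(P); Q <- l2_normalize_rows(Q) }
  S <- tcrossprod(P, Q)
  hits <- vapply(seq_len(n), function(i) {
    ord <- order(-S[i, ], seq_len(n)) # ties -> lower index first
    i %in% ord[seq_len(k)]
  }, logical(1))
  mean(hits)
}

#' Mean voxel-wise Pearson correlation
#'
#' Pearson correlation between predicted and observed responses, computed per
#' voxel across samples and averaged over voxels. Voxels with zero variance
#' in either argument are excluded and counted (attribute `n_excluded`).
#'
#' @param predicted `n x n_vox` predictions.
#' @param observed `n x n_vox` observations.
#' @return mean correlation in `[-1, 1]`, with attribute `n_excluded`.
#' @export
pcc <- function(predicted, observed) {
  predicted <- as.matrix(predicted); observed <- as.matrix(observed)
  if (!all(dim(predicted) == dim(observed)))
    nf_shape_error("predicted and observed must have identical shapes")
  if (nrow(predicted) < 2)
    nf_degenerate_error("need >= 2 samples per voxel for a correlation")
  sd_p <- apply(predicted, 2, stats::sd)
  sd_o <- apply(observed, 2, stats::sd)
  keep <- sd_p > 0 & sd_o > 0
  if (!any(keep))
    nf_degenerate_error("all voxels have zero variance")
  r <- vapply(which(keep), function(v) {
    stats::cor(predicted[, v], observed[, v])
  }, numeric(1))
  structure(mean(r), n_excluded = sum(!keep))
}

#' Intersection over union of two binary masks
#'
#' `|A & B| / |A | B|`; defined as 0 (with a message) when both masks are
#' empty.
#'
#' @param mask_a,mask_b logical/0-1 arrays of identical shape.
#' @return ratio in `[0, 1]`.
#' @export
iou <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a) %||% length(mask_a),
                 dim(mask_b) %||% length(mask_b)))
    nf_shape_error("masks must have identical shapes")
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  uni <- sum(a | b)
  if (uni == 0) {
    message("iou: both masks empty; returning 0")
    return(0)
  }
  sum(a & b) / uni
}

#' Mean IoU over classes
#'
#' Unweighted mean of per-class IoU values.
#'
#' @param per_class_ious numeric vector of per-class IoUs (length >= 1).
#' @return mean ratio.
#' @export
mean_iou <- function(per_class_ious) {
  if (length(per_class_ious) == 0)
    nf_degenerate_error("mean_iou needs at least one class")
  mean(per_class_ious)
}

#' Average precision from ordered precision/recall points
#'
#' The discrete sum `sum_i Precision_i * (Recall_i - Recall_{i-1})` with
#' `Recall_0 = 0`; recalls must be nondecreasing in `[0, 1]`.
#'
#' @param precision numeric vector of precision values.
#' @param recall numeric vector of matching recall values (nondecreasing).
#' @return average precision in `[0, 1]`.
#' @export
average_precision <- function(precision, recall) {
  if (length(precision) != length(recall))
    nf_shape_error("precision and recall must have equal length")
  if (length(recall) == 0)
    nf_degenerate_error("average_precision needs at least one point")
  if (any(recall < 0 | recall > 1))
    nf_input_error("recall values must lie in [0, 1]")
  if (any(diff(recall) < 0))
    nf_input_error("recall values must be nondecreasing")
  sum(precision * diff(c(0, recall)))
}
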