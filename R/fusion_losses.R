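# Cross-modal objectives: the symmetric temperature-scaled contrastive loss
# over global features, the ROI-level fMRI-guided loss over local features,
# their weighted sum, and the cross-modal fusion transformer block.

#' Loss configuration
#'
#' @param sigma contrastive temperature (> 0); default 0.07, the usual
#'   contrastive-pretraining convention (the method itself states no value).
#' @param lambda_con weight of the contrastive loss (>= 0).
#' @param lambda_bfg weight of the fMRI-guided loss (>= 0).
#' @param normalize_features unit-normalize feature rows before dot products
#'   (default TRUE; raw dot products overflow at sigma ~ 0.07).
#' @param bfg_batch_norm also divide the fMRI-guided loss by the batch size
#'   `n` (the printed form divides by the ROI count only, so it scales
#'   linearly with `n`; default FALSE = printed form).
#' @return object of class `nf_loss_config`.
#' @export
loss_config <- function(sigma = 0.07, lambda_con = 1, lambda_bfg = 1,
                        normalize_features = TRUE, bfg_batch_norm = FALSE) {
  if (!is.numeric(sigma) || sigma <= 0) nf_config_error("sigma must be > 0")
  if (lambda_con < 0 || lambda_bfg < 0)
    nf_config_error("loss weights must be >= 0")
  structure(list(sigma = sigma, lambda_con = lambda_con,
                 lambda_bfg = lambda_bfg,
                 normalize_features = isTRUE(normalize_features),
                 bfg_batch_norm = isTRUE(bfg_batch_norm)),
            class = "nf_loss_config")
}

#' Symmetric contrastive loss over matched global features
#'
#' The mean over samples of the cross-entropy of picking the matched partner
#' under a temperature-scaled softmax over dot-product similarities, summed
#' over both directions (image -> fMRI and fMRI -> image):
#' `L = -(1/n) sum_i log softmax_j(p_i . q_j / sigma)[i]
#'      -(1/n) sum_i log softmax_j(q_i . p_j / sigma)[i]`.
#' Computed with log-sum-exp; always nonnegative; zero iff every matched pair
#' holds all softmax mass.
#'
#' @param P `n x d` visual global features.
#' @param Q `n x d` fMRI global features.
#' @param sigma temperature (> 0).
#' @param normalize unit-normalize rows first (default TRUE).
#' @return scalar loss.
#' @export
contrastive_loss <- function(P, Q, sigma = 0.07, normalize = TRUE) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q)))
    nf_shape_error("P (%dx%d) and Q (%dx%d) must match",
                   nrow(P), ncol(P), nrow(Q), ncol(Q))
  n <- nrow(P)
  if (n == 0) nf_degenerate_error("contrastive loss needs n >= 1 samples")
  check_finite(P, "P"); check_finite(Q, "Q")
  if (normalize) { P <- l2_normalize_rows(P); Q <- l2_normalize_rows(Q) }
  S <- tcrossprod(P, Q) / sigma
  lse_rows <- apply(S, 1, logsumexp)
  lse_cols <- apply(S, 2, logsumexp)
  d <- diag(S)
  mean(lse_rows - d) + mean(lse_cols - d)
}

#' fMRI-guided loss over per-ROI local features
#'
#' For every sample `i` and ROI `k`, a softmax over the candidate brain-ROI
#' features `g` of the dot product with the image local feature, normalized
#' by the ROI count:
#' `L = -(1/N_r) sum_i sum_k log[ exp(p_ik . q_ik) / sum_g exp(p_ik . q_ig) ]`.
#' The printed normalization divides by `N_r` only, so the loss grows
#' linearly with the batch; `batch_norm = TRUE` additionally divides by `n`.
#'
#' @param P_local `n x N_r x d` visual local features.
#' @param Q_roi `n x N_r x d` fMRI per-ROI features.
#' @param normalize unit-normalize feature vectors first (default TRUE).
#' @param batch_norm divide by `n` as well (default FALSE = printed form).
#' @return scalar loss.
#' @export
fmri_guided_loss <- function(P_local, Q_roi, normalize = TRUE,
                             batch_norm = FALSE) {
  dp <- dim(P_local); dq <- dim(Q_roi)
  if (length(dp) != 3 || length(dq) != 3 || !all(dp == dq))
    nf_shape_error("P_local and Q_roi must be matching n x N_r x d arrays")
  n <- dp[1]; nr <- dp[2]
  if (nr < 1) nf_degenerate_error("need N_r >= 1 ROIs")
  total <- 0
  for (i in seq_len(n)) {
    Pi <- matrix(P_local[i, , ], nr)
    Qi <- matrix(Q_roi[i, , ], nr)
    if (normalize) { Pi <- l2_normalize_rows(Pi); Qi <- l2_normalize_rows(Qi) }
    S <- tcrossprod(Pi, Qi)
    total <- total + sum(apply(S, 1, logsumexp) - diag(S))
  }
  out <- total / nr
  if (batch_norm) out <- out / n
  out
}

#' Weighted total training objective
#'
#' @param lcon contrastive-loss value.
#' @param lbfg fMRI-guided-loss value.
#' @param cfg an [loss_config()].
#' @return `lambda_con * lcon + lambda_bfg * lbfg`.
#' @export
total_loss <- function(lcon, lbfg, cfg) {
  if (!inherits(cfg, "nf_loss_config")) cfg <- do.call(loss_config, cfg)
  if (!is.finite(lcon) || !is.finite(lbfg))
    nf_numeric_error("non-finite loss component (lcon=%s, lbfg=%s)",
                     format(lcon), format(lbfg))
  cfg$lambda_con * lcon + cfg$lambda_bfg * lbfg
}

#' Parameters of the cross-modal fusion block
#'
#' @param d model dimension.
#' @param n_roi ROI count.
#' @param n_heads attention heads.
#' @param seed RNG seed.
#' @param symmetric_types use identical type embeddings for the two
#'   modalities (mainly for permutation tests; default FALSE).
#' @return parameter list with `types` (`4 x d` modality-type embeddings:
#'   visual-global, fmri-global, visual-local, fmri-roi) and `block`.
#' @export
fuse_params <- function(d, n_roi = 6, n_heads = 4, seed = 1,
                        symmetric_types = FALSE) {
  types <- with_seed(derive_seed(seed, "fuse_types"), {
    tp <- matrix(stats::rnorm(4 * d, sd = 0.1), 4, d)
    if (symmetric_types) { tp[2, ] <- tp[1, ]; tp[4, ] <- tp[3, ] }
    tp
  })
  list(types = types,
       block = trans_block_params(d, n_heads, seed = derive_seed(seed, "fuse_block")),
       n_roi = as.integer(n_roi))
}

#' Fuse visual and fMRI features with one transformer encoder layer
#'
#' Assembles, per sample, the token sequence
#' `[global-visual, global-fMRI, N_r local-visual, N_r ROI-fMRI]`, adds a
#' learned modality-type embedding to every token, applies one standard
#' transformer block, and mean-pools the output tokens.
#'
#' @param visual an [encode_image()] result (or list with `global` `n x d`,
#'   `local` `n x N_r x d`).
#' @param fmri list with `global` (`n x d`) and `per_roi` (`n x N_r x d`).
#' @param params an [fuse_params()] list.
#' @return list with `pooled` (`n x d`) and `tokens`
#'   (`n x (2 + 2 N_r) x d` fused token sequences).
#' @export
fuse <- function(visual, fmri, params) {
  Pg <- as.matrix(visual$global); Qg <- as.matrix(fmri$global)
  Pl <- visual$local; Qr <- fmri$per_roi
  nr <- params$n_roi
  if (ncol(Pg) != ncol(Qg))
    nf_shape_error("modality dimensions differ: %d vs %d", ncol(Pg), ncol(Qg))
  if (dim(Pl)[2] != nr || dim(Qr)[2] != nr)
    nf_shape_error("local feature ROI count != %d", nr)
  n <- nrow(Pg); d <- ncol(Pg)
  n_tok <- 2L + 2L * nr
  pooled <- matrix(0, n, d)
  tokens <- array(0, c(n, n_tok, d))
  for (i in seq_len(n)) {
    X <- rbind(
      Pg[i, ] + params$types[1, ],
      Qg[i, ] + params$types[2, ],
      sweep(matrix(Pl[i, , ], nr), 2, params$types[3, ], "+"),
      sweep(matrix(Qr[i, , ], nr), 2, params$types[4, ], "+")
    )
    out <- trans_block(list(content = X, true_len = n_tok), params$block)$content
    tokens[i, , ] <- out
    pooled[i, ] <- colMeans(out)
  }
  list(pooled = pooled, tokens = tokens)
}
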