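# Joint cross-modal model: ties together the voxel tokenizer, the Timeformer,
# the visual encoder, the shared-space projection heads, the fusion block and
# the voxel-encoding head. Modality symmetry (equal shared-space dimension on
# both sides) is enforced at construction.

#' Construct the joint cross-modal model
#'
#' @param n_vox number of voxels the fMRI branch expects.
#' @param n_roi ROI count (default 6).
#' @param d shared-space dimension (default 32).
#' @param img_size image side length (default 224).
#' @param conv_kernel,conv_stride 1D tokenizer kernel/stride (defaults 32/16).
#' @param tf an [timeformer_config()] (its `d` must equal `d`).
#' @param backbone an [backbone_spec()] (its `d` must equal `d`).
#' @param seed RNG seed for all parameter initialisation.
#' @return object of class `nf_model`.
#' @export
nf_model <- function(n_vox, n_roi = 6, d = 32, img_size = 224,
                     conv_kernel = 32, conv_stride = 16,
                     tf = timeformer_config(d = d),
                     backbone = backbone_spec(d = d), seed = 1) {
  if (tf$d != d)
    nf_shape_error("timeformer dimension (%d) != model dimension (%d)", tf$d, d)
  if (backbone$d != d)
    nf_shape_error("backbone dimension (%d) != model dimension (%d)",
                   backbone$d, d)
  q_proj <- with_seed(derive_seed(seed, "q_proj"), {
    list(W = init_mat(d, d), b = numeric(d))
  })
  enc_head <- with_seed(derive_seed(seed, "enc_head"), {
    list(W = init_mat(d, n_vox), b = numeric(n_vox))
  })
  structure(list(
    n_vox = as.integer(n_vox), n_roi = as.integer(n_roi), d = as.integer(d),
    img_size = as.integer(img_size),
    coord = coord_embed_params(d, seed),
    conv = conv1d_params(d, conv_kernel, conv_stride, seed),
    tf_cfg = tf,
    tf_params = timeformer_params(tf, seed),
    vision = vision_params(backbone, n_roi, img_size, seed),
    fuse = fuse_params(d, n_roi, tf$n_heads, seed),
    q_proj = q_proj,
    enc_head = enc_head,
    seed = as.integer(seed)
  ), class = "nf_model")
}

#' Encode a batch of voxel responses with the fMRI branch
#'
#' Tokenizes each sample's voxel amplitude vector (1D conv + coordinate
#' embedding fusion), runs the Timeformer stack, and returns the global
#' feature (final token mean), the ROI-pooled final tokens before the ROI
#' head, and the projected per-ROI features.
#'
#' @param model an [nf_model()].
#' @param grid the [make_voxel_grid()] the responses live on.
#' @param responses `n x n_vox` response matrix.
#' @return list with `global` (`n x d`), `roi_pooled` (`n x n_roi x d`,
#'   pre-head), `per_roi` (`n x n_roi x d`, after the ROI head).
#' @export
fmri_encode <- function(model, grid, responses) {
  responses <- as.matrix(responses)
  if (ncol(responses) != grid$n_vox)
    nf_shape_error("responses have %d voxels, grid has %d",
                   ncol(responses), grid$n_vox)
  n <- nrow(responses); d <- model$d
  emb <- embed_coords(grid$coords, model$coord)
  rmap <- conv_windows(grid$n_vox, model$conv$kernel, model$conv$stride)
  pooled_emb <- pool_embedding(emb, rmap)
  Wfrac <- roi_overlap_fractions(rmap, grid$roi_labels, grid$n_roi)
  Wnorm <- Wfrac / rowSums(Wfrac)
  global <- matrix(0, n, d)
  roi_pooled <- array(0, c(n, grid$n_roi, d))
  for (i in seq_len(n)) {
    tok <- tokenize_signal(responses[i, ], model$conv)
    tok$tokens <- tok$tokens + pooled_emb
    ff <- timeformer_forward(tok$tokens, model$tf_cfg, model$tf_params)
    global[i, ] <- ff$global
    roi_pooled[i, , ] <- Wnorm %*% ff$tokens
  }
  per_roi <- array(0, c(n, grid$n_roi, d))
  rh <- model$tf_params$roi_head
  for (k in seq_len(grid$n_roi)) {
    per_roi[, k, ] <- sweep(matrix(roi_pooled[, k, ], n) %*% rh$W, 2, rh$b, "+")
  }
  list(global = global, roi_pooled = roi_pooled, per_roi = per_roi)
}

#' Precompute frozen-branch features for training
#'
#' Runs the (frozen) visual backbone and fMRI branch once over a pair set so
#' that training epochs only touch the trainable heads. Each cached feature
#' block is z-scored per dimension (zero-variance dimensions left unscaled):
#' the frozen random features have badly skewed raw scales, and the
#' standardization — a deterministic function of the dataset — conditions the
#' head optimization without changing what is representable.
#'
#' @param model an [nf_model()].
#' @param pairs an [generate_pairs()] result.
#' @param standardize z-score the cached blocks (default TRUE).
#' @return feature cache list (`gvec`, `flat`, `fmri_global`, `roi_pooled`,
#'   `responses`, `n`).
#' @export
precompute_features <- function(model, pairs, standardize = TRUE) {
  vis <- tiny_conv_features(pairs$images, model$vision)
  fm <- fmri_encode(model, pairs$grid, pairs$responses)
  out <- list(gvec = vis$gvec, flat = vis$flat,
              fmri_global = fm$global, roi_pooled = fm$roi_pooled,
              responses = as.matrix(pairs$responses), n = nrow(vis$gvec))
  if (standardize && out$n > 1) {
    zs <- function(X) {
      mu <- colMeans(X)
      s <- sqrt(colMeans(sweep(X, 2, mu)^2))
      s[s < 1e-12] <- 1
      sweep(sweep(X, 2, mu), 2, s, "/")
    }
    out$gvec <- zs(out$gvec)
    out$flat <- zs(out$flat)
    out$fmri_global <- zs(out$fmri_global)
    for (k in seq_len(dim(out$roi_pooled)[2])) {
      out$roi_pooled[, k, ] <- zs(matrix(out$roi_pooled[, k, ], out$n))
    }
  }
  out
}

subset_features <- function(feats, idx) {
  list(gvec = feats$gvec[idx, , drop = FALSE],
       flat = feats$flat[idx, , drop = FALSE],
       fmri_global = feats$fmri_global[idx, , drop = FALSE],
       roi_pooled = feats$roi_pooled[idx, , , drop = FALSE],
       responses = feats$responses[idx, , drop = FALSE],
       n = length(idx))
}

# Forward pass of the trainable heads on cached features.
head_forward <- function(model, feats) {
  n <- feats$n; d <- model$d; nr <- model$n_roi
  h <- model$vision$heads
  P_glob <- sweep(feats$flat %*% h$W_g, 2, h$b_g, "+")
  Q_glob <- sweep(feats$fmri_global %*% model$q_proj$W, 2, model$q_proj$b, "+")
  P_loc <- array(0, c(n, nr, d))
  Q_roi <- array(0, c(n, nr, d))
  rh <- model$tf_params$roi_head
  for (k in seq_len(nr)) {
    P_loc[, k, ] <- sweep(feats$flat %*% h$W_l[[k]], 2, h$b_l[[k]], "+")
    Q_roi[, k, ] <- sweep(matrix(feats$roi_pooled[, k, ], n) %*% rh$W, 2, rh$b, "+")
  }
  list(P_glob = P_glob, Q_glob = Q_glob, P_loc = P_loc, Q_roi = Q_roi)
}

#' Shared-space global features of a pair set under a model
#'
#' @param model an [nf_model()].
#' @param feats a [precompute_features()] cache (optionally subset).
#' @param normalize unit-normalize rows (default TRUE).
#' @return list with `P` (visual) and `Q` (fMRI), both `n x d`.
#' @export
shared_features <- function(model, feats, normalize = TRUE) {
  hf <- head_forward(model, feats)
  P <- hf$P_glob; Q <- hf$Q_glob
  if (normalize) { P <- l2_normalize_rows(P); Q <- l2_normalize_rows(Q) }
  list(P = P, Q = Q)
}

#' Voxel-response predictions from the fused representation
#'
#' Routes the pre-fusion features through the fusion transformer block and a
#' linear encoding head to per-voxel predictions (the evaluation plumbing
#' behind the voxel-wise Pearson correlation metric).
#'
#' @param model an [nf_model()].
#' @param feats a [precompute_features()] cache (optionally subset).
#' @return `n x n_vox` prediction matrix.
#' @export
predict_responses <- function(model, feats) {
  hf <- head_forward(model, feats)
  fused <- fuse(list(global = hf$P_glob, local = hf$P_loc),
                list(global = hf$Q_glob, per_roi = hf$Q_roi),
                model$fuse)
  sweep(fused$pooled %*% model$enc_head$W, 2, model$enc_head$b, "+")
}
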