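# Desk-scale training of the joint objective. The convolutional backbone and
# the Timeformer body are frozen at their random initialisation
# (random-features regime); the trainable parameters are the cross-modal
# projection heads (visual global FC, per-ROI local heads, the fMRI ROI head
# and the fMRI shared-space projection) plus the linear encoding head. Their
# gradients under the total loss are computed analytically and applied with
# Adam. The auxiliary mean-squared term backpropagates to the encoding head
# only.

#' Training configuration
#'
#' @param lr Adam learning rate (>= 0). The method's stated full-scale value
#'   is 1e-4 over 100 epochs of large-scale data; that is the default. Desk
#'   -scale runs over a few hundred samples use `lr = 0.01` (see the methods
#'   vignette).
#' @param epochs number of epochs (>= 0; desk default 30).
#' @param batch_size minibatch size (default 32).
#' @param seed RNG seed controlling the split and batch shuffling.
#' @param loss an [loss_config()].
#' @param holdout_frac fraction of samples held out for evaluation
#'   (default 0.2).
#' @param mse_weight weight of the auxiliary mean-squared encoding term
#'   (default 0.1).
#' @return object of class `nf_train_config`.
#' @export
train_config <- function(lr = 1e-4, epochs = 30, batch_size = 32, seed = 1,
                         loss = loss_config(), holdout_frac = 0.2,
                         mse_weight = 0.1) {
  if (!is.numeric(lr) || lr < 0) nf_config_error("lr must be >= 0")
  if (!is.numeric(epochs) || epochs < 0 || epochs != round(epochs))
    nf_config_error("epochs must be a nonnegative integer")
  if (batch_size < 1) nf_config_error("batch_size must be >= 1")
  if (holdout_frac < 0 || holdout_frac >= 1)
    nf_config_error("holdout_frac must be in [0, 1)")
  if (!inherits(loss, "nf_loss_config")) loss <- do.call(loss_config, loss)
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 loss = loss, holdout_frac = holdout_frac,
                 mse_weight = mse_weight),
            class = "nf_train_config")
}

# ---- trainable parameter plumbing ------------------------------------------

get_theta <- function(model) {
  th <- list(W_g = model$vision$heads$W_g, b_g = model$vision$heads$b_g,
             q_W = model$q_proj$W, q_b = model$q_proj$b,
             roi_W = model$tf_params$roi_head$W,
             roi_b = model$tf_params$roi_head$b,
             enc_W = model$enc_head$W, enc_b = model$enc_head$b)
  for (k in seq_len(model$n_roi)) {
    th[[paste0("W_l", k)]] <- model$vision$heads$W_l[[k]]
    th[[paste0("b_l", k)]] <- model$vision$heads$b_l[[k]]
  }
  th
}

set_theta <- function(model, th) {
  model$vision$heads$W_g <- th$W_g; model$vision$heads$b_g <- th$b_g
  model$q_proj$W <- th$q_W; model$q_proj$b <- th$q_b
  model$tf_params$roi_head$W <- th$roi_W
  model$tf_params$roi_head$b <- th$roi_b
  model$enc_head$W <- th$enc_W; model$enc_head$b <- th$enc_b
  for (k in seq_len(model$n_roi)) {
    model$vision$heads$W_l[[k]] <- th[[paste0("W_l", k)]]
    model$vision$heads$b_l[[k]] <- th[[paste0("b_l", k)]]
  }
  model
}

norm_forward <- function(X, eps = 1e-12) {
  nrm <- pmax(sqrt(rowSums(X^2)), eps)
  list(Xh = X / nrm, nrm = nrm)
}

# Backprop through row-wise unit normalization: G is dL/dXh.
norm_backward <- function(G, Xh, nrm) {
  (G - rowSums(G * Xh) * Xh) / nrm
}

# Objective and analytic gradients of the trainable heads on cached features.
loss_and_grads <- function(model, feats, loss_cfg, mse_weight = 0.1,
                           want_grads = TRUE) {
  n <- feats$n; nr <- model$n_roi; d <- model$d
  hf <- head_forward(model, feats)
  normalize <- loss_cfg$normalize_features
  sigma <- loss_cfg$sigma

  # contrastive term over globals
  if (normalize) {
    pf <- norm_forward(hf$P_glob); qf <- norm_forward(hf$Q_glob)
    Ph <- pf$Xh; Qh <- qf$Xh
  } else { Ph <- hf$P_glob; Qh <- hf$Q_glob }
  S <- tcrossprod(Ph, Qh) / sigma
  lse_r <- apply(S, 1, logsumexp); lse_c <- apply(S, 2, logsumexp)
  lcon <- mean(lse_r - diag(S)) + mean(lse_c - diag(S))

  # ROI-guided term over locals
  lbfg <- 0
  dPl_h <- array(0, c(n, nr, d)); dQr_h <- array(0, c(n, nr, d))
  Pl_h <- array(0, c(n, nr, d)); Qr_h <- array(0, c(n, nr, d))
  Pl_nrm <- matrix(1, n, nr); Qr_nrm <- matrix(1, n, nr)
  for (i in seq_len(n)) {
    Pi <- matrix(hf$P_loc[i, , ], nr); Qi <- matrix(hf$Q_roi[i, , ], nr)
    if (normalize) {
      pfi <- norm_forward(Pi); qfi <- norm_forward(Qi)
      Pl_nrm[i, ] <- pfi$nrm; Qr_nrm[i, ] <- qfi$nrm
      Pi <- pfi$Xh; Qi <- qfi$Xh
    }
    Pl_h[i, , ] <- Pi; Qr_h[i, , ] <- Qi
    Si <- tcrossprod(Pi, Qi)
    lbfg <- lbfg + sum(apply(Si, 1, logsumexp) - diag(Si))
    if (want_grads) {
      dSi <- (row_softmax(Si) - diag(nr)) / nr
      dPl_h[i, , ] <- dSi %*% Qi
      dQr_h[i, , ] <- crossprod(dSi, Pi)
    }
  }
  lbfg <- lbfg / nr
  if (loss_cfg$bfg_batch_norm) {
    lbfg <- lbfg / n
    dPl_h <- dPl_h / n; dQr_h <- dQr_h / n
  }

  # encoding head on fused features (MSE auxiliary; stop-gradient into fusion)
  fused <- fuse(list(global = hf$P_glob, local = hf$P_loc),
                list(global = hf$Q_glob, per_roi = hf$Q_roi), model$fuse)
  Z <- fused$pooled
  pred <- sweep(Z %*% model$enc_head$W, 2, model$enc_head$b, "+")
  err <- pred - feats$responses
  mse <- mean(err^2)

  total <- total_loss(lcon, lbfg, loss_cfg)
  objective <- total + mse_weight * mse
  out <- list(lcon = lcon, lbfg = lbfg, mse = mse, total = total,
              objective = objective)
  if (!want_grads) return(out)

  lam_c <- loss_cfg$lambda_con; lam_b <- loss_cfg$lambda_bfg
  A <- row_softmax(S)
  B <- t(row_softmax(t(S)))
  dS <- ((A - diag(n)) + (B - diag(n))) / n
  dPh <- (dS %*% Qh) / sigma
  dQh <- (crossprod(dS, Ph)) / sigma
  dP <- if (normalize) norm_backward(dPh, Ph, pf$nrm) else dPh
  dQ <- if (normalize) norm_backward(dQh, Qh, qf$nrm) else dQh
  dP <- lam_c * dP; dQ <- lam_c * dQ

  g <- list(
    W_g = crossprod(feats$flat, dP), b_g = colSums(dP),
    q_W = crossprod(feats$fmri_global, dQ), q_b = colSums(dQ),
    roi_W = matrix(0, d, d), roi_b = numeric(d)
  )
  dpred <- 2 * err / length(err) * mse_weight
  g$enc_W <- crossprod(Z, dpred); g$enc_b <- colSums(dpred)
  for (k in seq_len(nr)) {
    Gp <- matrix(dPl_h[, k, ], n); Gq <- matrix(dQr_h[, k, ], n)
    if (normalize) {
      Gp <- norm_backward(Gp, matrix(Pl_h[, k, ], n), Pl_nrm[, k])
      Gq <- norm_backward(Gq, matrix(Qr_h[, k, ], n), Qr_nrm[, k])
    }
    Gp <- lam_b * Gp; Gq <- lam_b * Gq
    g[[paste0("W_l", k)]] <- crossprod(feats$flat, Gp)
    g[[paste0("b_l", k)]] <- colSums(Gp)
    g$roi_W <- g$roi_W + crossprod(matrix(feats$roi_pooled[, k, ], n), Gq)
    g$roi_b <- g$roi_b + colSums(Gq)
  }
  out$grads <- g
  out
}

adam_init <- function(theta) {
  list(m = lapply(theta, function(x) x * 0),
       v = lapply(theta, function(x) x * 0), t = 0L)
}

adam_step <- function(theta, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    theta[[nm]] <- theta[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(theta = theta, state = state)
}

#' Train the joint model on paired data
#'
#' Adam optimization of the weighted total objective over minibatches,
#' deterministic given the seed. A fixed fraction of samples is held out for
#' evaluation before training starts.
#'
#' @param pairs an [generate_pairs()] result (or any list with `images`,
#'   `grid`, `responses`).
#' @param model an [nf_model()]; built automatically when NULL.
#' @param cfg an [train_config()].
#' @param features optional [precompute_features()] cache to reuse (must
#'   match `model` and `pairs`).
#' @return object of class `nf_trained`: `model` (updated), `history`
#'   (per-epoch data frame with `l_con`, `l_bfg`, `mse`, `total`), `split`
#'   (`train`, `test` index vectors), `features`, `config`.
#' @export
train <- function(pairs, model = NULL, cfg = train_config(), features = NULL) {
  if (!inherits(cfg, "nf_train_config")) cfg <- do.call(train_config, cfg)
  n <- nrow(as.matrix(pairs$responses))
  if (n == 0) nf_degenerate_error("empty training set")
  if (is.null(model)) {
    model <- nf_model(n_vox = pairs$grid$n_vox, n_roi = pairs$grid$n_roi,
                      img_size = dim(pairs$images)[2], seed = cfg$seed)
  }
  if (is.null(features)) features <- precompute_features(model, pairs)

  n_test <- round(cfg$holdout_frac * n)
  test_idx <- if (n_test > 0) {
    with_seed(derive_seed(cfg$seed, "split"), sort(sample.int(n, n_test)))
  } else integer(0)
  train_idx <- setdiff(seq_len(n), test_idx)

  theta <- get_theta(model)
  state <- adam_init(theta)
  hist <- vector("list", cfg$epochs)
  for (e in seq_len(cfg$epochs)) {
    perm <- with_seed(derive_seed(cfg$seed, paste0("epoch", e)),
                      sample(train_idx))
    batches <- split(perm, ceiling(seq_along(perm) / cfg$batch_size))
    acc <- c(l_con = 0, l_bfg = 0, mse = 0, total = 0)
    for (b in seq_along(batches)) {
      fb <- subset_features(features, batches[[b]])
      model <- set_theta(model, theta)
      lg <- withCallingHandlers(
        loss_and_grads(model, fb, cfg$loss, cfg$mse_weight),
        nf_numeric_error = function(cond) {
          nf_numeric_error("non-finite loss in epoch %d, batch %d: %s",
                           e, b, conditionMessage(cond))
        }
      )
      if (!is.finite(lg$objective))
        nf_numeric_error("non-finite loss in epoch %d, batch %d", e, b)
      st <- adam_step(theta, lg$grads, state, cfg$lr)
      theta <- st$theta; state <- st$state
      acc <- acc + c(lg$lcon, lg$lbfg, lg$mse, lg$total)
    }
    hist[[e]] <- as.list(acc / length(batches))
  }
  model <- set_theta(model, theta)
  history <- if (cfg$epochs > 0) {
    do.call(rbind, lapply(seq_len(cfg$epochs), function(e) {
      data.frame(epoch = e, hist[[e]])
    }))
  } else {
    data.frame(epoch = integer(0), l_con = numeric(0), l_bfg = numeric(0),
               mse = numeric(0), total = numeric(0))
  }
  structure(list(model = model, history = history,
                 split = list(train = train_idx, test = test_idx),
                 features = features, config = cfg),
            class = "nf_trained")
}

#' Evaluate a trained model on its held-out samples
#'
#' @param trained an [train()] result.
#' @param ks top-k levels for retrieval (default 1 and 5).
#' @return list of class `nf_eval_report`: `retrieval_top1`,
#'   `retrieval_top5`, `mean_pcc`, `loss_history`, `n_test`.
#' @export
evaluate <- function(trained, ks = c(1, 5)) {
  idx <- trained$split$test
  if (length(idx) == 0) nf_degenerate_error("no held-out samples to evaluate")
  feats <- subset_features(trained$features, idx)
  sf <- shared_features(trained$model, feats,
                        normalize = trained$config$loss$normalize_features)
  n <- length(idx)
  top1 <- retrieval_accuracy(sf$P, sf$Q, k = min(ks[1], n))
  top5 <- retrieval_accuracy(sf$P, sf$Q, k = min(ks[2] %||% 5, n))
  pred <- predict_responses(trained$model, feats)
  mpcc <- pcc(pred, feats$responses)
  structure(list(retrieval_top1 = top1, retrieval_top5 = top5,
                 mean_pcc = mpcc, loss_history = trained$history,
                 n_test = n),
            class = "nf_eval_report")
}

#' Matched-minus-mismatched ROI-level alignment score
#'
#' Mean cosine similarity between each image local feature and its matched
#' brain-ROI feature, minus the mean similarity to the mismatched ROIs —
#' the quantity the ROI-guided loss pushes up.
#'
#' @param model an [nf_model()].
#' @param feats a [precompute_features()] cache (optionally subset).
#' @return scalar score (positive = matched pairs more similar).
#' @export
roi_alignment_score <- function(model, feats) {
  hf <- head_forward(model, feats)
  n <- feats$n; nr <- model$n_roi
  matched <- 0; mismatched <- 0
  for (i in seq_len(n)) {
    Pi <- l2_normalize_rows(matrix(hf$P_loc[i, , ], nr))
    Qi <- l2_normalize_rows(matrix(hf$Q_roi[i, , ], nr))
    S <- tcrossprod(Pi, Qi)
    matched <- matched + mean(diag(S))
    mismatched <- mismatched + (sum(S) - sum(diag(S))) / (nr * (nr - 1))
  }
  (matched - mismatched) / n
}
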