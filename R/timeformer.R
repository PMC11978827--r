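# Sliced-window transformer over the tokenized fMRI signal. Each layer slices
# its input sequence into windows of width w sliding with stride s, runs a
# standard pre-norm transformer block inside every window (padded positions
# masked out of attention), and reassembles a full-length sequence by
# averaging overlapping window outputs position-wise. Attention cost per layer
# is n_windows * w^2 query-key pairs, strictly below L^2 once L > w.

#' Timeformer configuration
#'
#' @param w window width in tokens (default 64). May be a length-`h` vector
#'   for per-layer widths.
#' @param s window stride in tokens (default 32); `1 <= s <= w`. May be a
#'   length-`h` vector.
#' @param h number of stacked layers (default 2).
#' @param d model dimension (default 32); divisible by `n_heads`.
#' @param n_heads attention heads (default 4).
#' @param pad_policy `"pad_last"` (default: right-zero-pad one extra window so
#'   every token is covered) or `"drop_last"` (full windows only; uncovered
#'   tokens trigger a warning).
#' @return object of class `nf_timeformer_config`.
#' @export
timeformer_config <- function(w = 64, s = 32, h = 2, d = 32, n_heads = 4,
                              pad_policy = c("pad_last", "drop_last")) {
  pad_policy <- match.arg(pad_policy)
  if (h < 1) nf_config_error("h must be >= 1")
  w <- as.integer(rep_len(w, h)); s <- as.integer(rep_len(s, h))
  if (any(s < 1) || any(s > w))
    nf_config_error("stride must satisfy 1 <= s <= w (got s=%s, w=%s)",
                    paste(s, collapse = ","), paste(w, collapse = ","))
  if (d %% n_heads != 0)
    nf_config_error("d (%d) must be divisible by n_heads (%d)", d, n_heads)
  structure(list(w = w, s = s, h = as.integer(h), d = as.integer(d),
                 n_heads = as.integer(n_heads), pad_policy = pad_policy),
            class = "nf_timeformer_config")
}

#' Window start indices and coverage for sliced-window processing
#'
#' For a sequence of length `L`, full windows start at `0, s, 2s, ...` —
#' `floor((L - w)/s) + 1` of them when `L >= w`. Under `pad_last`, one extra
#' right-zero-padded window is appended iff the full windows do not reach
#' index `L - 1` (including the `L < w` case), so the union of true ranges is
#' always `[0, L)`. Under `drop_last` uncovered trailing tokens produce a
#' warning.
#'
#' @param L sequence length (> 0).
#' @param w window width.
#' @param s stride, `1 <= s <= w`.
#' @param pad_policy `"pad_last"` or `"drop_last"`.
#' @return integer matrix with columns `start` (0-based) and `true_len`.
#' @export
window_starts <- function(L, w, s, pad_policy = "pad_last") {
  if (L <= 0) nf_degenerate_error("empty token sequence (L = 0)")
  if (s < 1 || s > w) nf_config_error("need 1 <= s <= w")
  if (L >= w) {
    n_full <- (L - w) %/% s + 1L
    starts <- (seq_len(n_full) - 1L) * s
    lens <- rep(w, n_full)
    covered <- starts[n_full] + w
    if (covered < L) {
      if (pad_policy == "pad_last") {
        starts <- c(starts, n_full * s)
        lens <- c(lens, L - n_full * s)
      } else {
        warning(sprintf("drop_last leaves %d token(s) uncovered", L - covered))
      }
    }
  } else {
    if (pad_policy == "pad_last") {
      starts <- 0L; lens <- L
    } else {
      warning(sprintf("drop_last leaves %d token(s) uncovered", L))
      starts <- integer(0); lens <- integer(0)
    }
  }
  cbind(start = as.integer(starts), true_len = as.integer(lens))
}

#' Slice a token sequence into overlapping windows
#'
#' @param tokens `L x d` matrix.
#' @param cfg an [timeformer_config()] (its first-layer `w`, `s` are used) or
#'   a list with scalar `w`, `s`, `pad_policy`.
#' @return list of window slices, each with `content` (`w x d`, right-zero
#'   padded), `start` (0-based) and `true_len`; ordered by start.
#' @export
slice_windows <- function(tokens, cfg) {
  tokens <- as.matrix(tokens)
  L <- nrow(tokens)
  w <- cfg$w[1]; s <- cfg$s[1]
  st <- window_starts(L, w, s, cfg$pad_policy %||% "pad_last")
  lapply(seq_len(nrow(st)), function(i) {
    start <- unname(st[i, 1]); tl <- unname(st[i, 2])
    content <- matrix(0, w, ncol(tokens))
    content[seq_len(tl), ] <- tokens[(start + 1):(start + tl), , drop = FALSE]
    list(content = content, start = start, true_len = tl)
  })
}

#' Parameters of one transformer block
#'
#' Pre-norm multi-head self-attention followed by a pre-norm GELU feed-forward
#' of width `ffn_mult * d`, both with residual connections.
#'
#' @param d model dimension.
#' @param n_heads attention heads.
#' @param seed RNG seed.
#' @param ffn_mult feed-forward expansion factor (default 4).
#' @return parameter list.
#' @export
trans_block_params <- function(d, n_heads = 4, seed = 1, ffn_mult = 4) {
  with_seed(derive_seed(seed, "trans_block"), {
    list(
      Wq = init_mat(d, d), Wk = init_mat(d, d), Wv = init_mat(d, d),
      Wo = init_mat(d, d), bo = numeric(d),
      ln1_g = rep(1, d), ln1_b = numeric(d),
      ln2_g = rep(1, d), ln2_b = numeric(d),
      W1 = init_mat(d, ffn_mult * d), b1 = numeric(ffn_mult * d),
      W2 = init_mat(ffn_mult * d, d), b2 = numeric(d),
      n_heads = as.integer(n_heads)
    )
  })
}

layer_norm <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  v <- rowMeans((X - mu)^2)
  sweep(sweep((X - mu) / sqrt(v + eps), 2, g, "*"), 2, b, "+")
}

#' Apply one transformer block to a window slice
#'
#' Padded positions are masked out of attention: no real position assigns any
#' attention mass to a padded key. Padded output rows are computed but carry
#' no meaning and are discarded at reassembly.
#'
#' @param slice a [slice_windows()] element (`content` `w x d`, `true_len`).
#' @param params a [trans_block_params()] list.
#' @return the slice with transformed `content` (same shape).
#' @export
trans_block <- function(slice, params) {
  X <- slice$content
  w <- nrow(X); d <- ncol(X)
  if (ncol(params$Wq) != d)
    nf_shape_error("block dimension %d != token dimension %d", ncol(params$Wq), d)
  tl <- slice$true_len %||% w
  if (tl > w) nf_shape_error("true_len (%d) exceeds window width (%d)", tl, w)
  nh <- params$n_heads
  dh <- d %/% nh
  H <- layer_norm(X, params$ln1_g, params$ln1_b)
  Q <- H %*% params$Wq; K <- H %*% params$Wk; V <- H %*% params$Wv
  attn <- matrix(0, w, d)
  key_mask <- seq_len(w) <= tl
  for (h in seq_len(nh)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh)
    S[, !key_mask] <- -Inf
    A <- row_softmax(S)
    attn[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  X <- X + sweep(attn %*% params$Wo, 2, params$bo, "+")
  H2 <- layer_norm(X, params$ln2_g, params$ln2_b)
  X <- X + sweep(gelu(sweep(H2 %*% params$W1, 2, params$b1, "+")) %*% params$W2,
                 2, params$b2, "+")
  slice$content <- X
  slice
}

# Attention weights of one block on one slice (head-averaged), for testing
# the masking contract.
attention_weights <- function(slice, params) {
  X <- slice$content
  w <- nrow(X); d <- ncol(X)
  nh <- params$n_heads; dh <- d %/% nh
  H <- layer_norm(X, params$ln1_g, params$ln1_b)
  Q <- H %*% params$Wq; K <- H %*% params$Wk
  key_mask <- seq_len(w) <= (slice$true_len %||% w)
  acc <- matrix(0, w, w)
  for (h in seq_len(nh)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh)
    S[, !key_mask] <- -Inf
    acc <- acc + row_softmax(S)
  }
  acc / nh
}

#' Parameters of the full Timeformer stack
#'
#' @param cfg an [timeformer_config()].
#' @param seed RNG seed.
#' @return list with `layers` (one [trans_block_params()] per layer) and
#'   `roi_head` (`W` `d x d`, `b`) projecting ROI-pooled tokens.
#' @export
timeformer_params <- function(cfg, seed = 1) {
  layers <- lapply(seq_len(cfg$h), function(l) {
    trans_block_params(cfg$d, cfg$n_heads, seed = derive_seed(seed, paste0("layer", l)))
  })
  roi_head <- with_seed(derive_seed(seed, "roi_head"), {
    list(W = init_mat(cfg$d, cfg$d), b = numeric(cfg$d))
  })
  list(layers = layers, roi_head = roi_head)
}

# Position-wise average of overlapping window outputs over true positions.
reassemble_windows <- function(slices, L, d) {
  acc <- matrix(0, L, d)
  cnt <- numeric(L)
  for (sl in slices) {
    idx <- (sl$start + 1):(sl$start + sl$true_len)
    acc[idx, ] <- acc[idx, , drop = FALSE] + sl$content[seq_len(sl$true_len), , drop = FALSE]
    cnt[idx] <- cnt[idx] + 1
  }
  if (any(cnt == 0))
    nf_degenerate_error("token position %d covered by no window", which(cnt == 0)[1] - 1L)
  acc / cnt
}

#' Run the sliced-window transformer stack over a token sequence
#'
#' Layer `l` slices its input with `(w_l, s_l)`, applies [trans_block()] to
#' every slice, and reassembles a full-length sequence by averaging
#' overlapping window outputs position-wise. After `h` layers the global
#' feature is the token mean of the final sequence; per-ROI features are the
#' [roi_pool()] of the final sequence projected by a linear head (requires
#' `grid` and the tokenizer's `receptive_map`).
#'
#' @param tokens `L x d` token matrix (or an `nf_tokenized` object, in which
#'   case its receptive map is used automatically).
#' @param cfg an [timeformer_config()].
#' @param params an [timeformer_params()] list.
#' @param grid optional [make_voxel_grid()] for per-ROI features.
#' @param receptive_map optional `n_tok x 2` 0-based half-open ranges
#'   (taken from `tokens` when it is an `nf_tokenized`).
#' @return object of class `nf_fmri_feature`: `global` (length `d`),
#'   `per_roi` (`n_roi x d` or NULL), `tokens` (final `L x d` sequence).
#' @export
timeformer_forward <- function(tokens, cfg, params, grid = NULL,
                               receptive_map = NULL) {
  if (inherits(tokens, "nf_tokenized")) {
    receptive_map <- receptive_map %||% tokens$receptive_map
    tokens <- tokens$tokens
  }
  tokens <- as.matrix(tokens)
  L <- nrow(tokens); d <- ncol(tokens)
  if (d != cfg$d) nf_shape_error("token dim %d != cfg$d %d", d, cfg$d)
  X <- tokens
  for (l in seq_len(cfg$h)) {
    layer_cfg <- list(w = cfg$w[l], s = cfg$s[l], pad_policy = cfg$pad_policy)
    slices <- slice_windows(X, layer_cfg)
    slices <- lapply(slices, trans_block, params = params$layers[[l]])
    X <- reassemble_windows(slices, L, d)
  }
  per_roi <- NULL
  if (!is.null(grid)) {
    if (is.null(receptive_map))
      nf_input_error("per-ROI features need the tokenizer receptive map")
    pooled <- roi_pool(list(tokens = X, receptive_map = receptive_map), grid)
    per_roi <- sweep(pooled %*% params$roi_head$W, 2, params$roi_head$b, "+")
  }
  structure(list(global = colMeans(X), per_roi = per_roi, tokens = X),
            class = "nf_fmri_feature")
}

#' Closed-form attention cost of one Timeformer layer
#'
#' Number of query-key pairs evaluated: `n_windows * w^2`, the windowed
#' -attention cost that replaces the quadratic `L^2` of full attention.
#'
#' @param L sequence length.
#' @param w window width.
#' @param s stride.
#' @param pad_policy padding policy.
#' @return integer pair count.
#' @export
attention_pair_count <- function(L, w, s, pad_policy = "pad_last") {
  st <- window_starts(L, w, s, pad_policy)
  nrow(st) * w^2
}
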