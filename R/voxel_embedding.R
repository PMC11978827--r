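# Brain 3D voxel embedding: a linear map lifts each voxel's (x, y, z) lattice
# coordinate into the model space; the whole-brain amplitude sequence at one
# time step is tokenized by a strided 1D convolution; the two are fused by
# adding, to each conv token, the mean coordinate embedding over the token's
# receptive field. Voxels are always serialized in ascending (z, y, x) order
# (fixed at grid construction).

#' Parameters of the coordinate embedding (a 3 -> d affine map)
#'
#' @param d embedding dimension.
#' @param seed RNG seed for initialisation.
#' @param bias include a bias term (default TRUE).
#' @return list with `W` (`3 x d`), `b` (length-`d`; zeros when `bias = FALSE`).
#' @export
coord_embed_params <- function(d, seed = 1, bias = TRUE) {
  with_seed(derive_seed(seed, "coord_embed"), {
    list(W = init_mat(3L, d),
         b = if (bias) stats::rnorm(d, sd = 0.01) else numeric(d))
  })
}

#' Embed voxel coordinates linearly
#'
#' Each voxel's feature is exactly the affine image of its (optionally
#' normalized) coordinate triple; it never depends on signal values.
#' Normalization rescales each axis to `[0, 1]` over the given voxels so
#' embeddings are grid-size invariant; disable it to make the map a plain
#' affine function of the raw lattice coordinates.
#'
#' @param coords `n x 3` coordinate matrix.
#' @param params a [coord_embed_params()] list (`W` `3 x d`, `b` length `d`).
#' @param normalize rescale each axis to `[0, 1]` first (default TRUE).
#' @return `n x d` matrix of per-voxel features.
#' @export
embed_coords <- function(coords, params, normalize = TRUE) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) nf_shape_error("coords must have 3 columns, got %d", ncol(coords))
  if (!is.matrix(params$W) || nrow(params$W) != 3)
    nf_shape_error("coordinate map must be 3 x d, got %d x %d",
                   nrow(params$W), ncol(params$W))
  if (length(params$b) != ncol(params$W))
    nf_shape_error("coordinate bias length %d != d = %d",
                   length(params$b), ncol(params$W))
  X <- coords
  if (normalize) {
    rng <- apply(X, 2, range)
    span <- rng[2, ] - rng[1, ]
    span[span == 0] <- 1
    X <- sweep(sweep(X, 2, rng[1, ]), 2, span, "/")
  }
  sweep(X %*% params$W, 2, params$b, "+")
}

#' Concatenate per-voxel features into the whole-brain joint representation
#'
#' Row `i` of the input occupies positions `d*i .. d*i + d - 1` (0-based) of
#' the output, i.e. the output is the ordered concatenation of voxel features
#' in voxel index order.
#'
#' @param per_voxel `n_vox x d` feature matrix (or a list of equal-length
#'   vectors).
#' @return numeric vector of length `n_vox * d`.
#' @export
concat_voxels <- function(per_voxel) {
  if (is.list(per_voxel) && !is.data.frame(per_voxel)) {
    lens <- lengths(per_voxel)
    if (length(unique(lens)) > 1)
      nf_shape_error("ragged per-voxel feature dimensions: %s",
                     paste(unique(lens), collapse = ", "))
    per_voxel <- do.call(rbind, per_voxel)
  }
  per_voxel <- as.matrix(per_voxel)
  if (nrow(per_voxel) == 0) nf_shape_error("empty per-voxel feature list")
  as.vector(t(per_voxel))
}

#' Parameters of the 1D-convolution tokenizer
#'
#' One input channel (the voxel amplitude sequence), `d` output channels.
#'
#' @param d output channels (must match the coordinate embedding dimension).
#' @param kernel window length in voxels (default 32).
#' @param stride step in voxels (default 16).
#' @param seed RNG seed.
#' @return list with `W` (`d x kernel`), `b` (length `d`), `kernel`, `stride`.
#' @export
conv1d_params <- function(d, kernel = 32, stride = 16, seed = 1) {
  if (kernel < 1 || stride < 1) nf_config_error("kernel and stride must be >= 1")
  with_seed(derive_seed(seed, "conv1d"), {
    list(W = t(init_mat(kernel, d)), b = numeric(d),
         kernel = as.integer(kernel), stride = as.integer(stride))
  })
}

# Half-open receptive ranges [start, end) of the strided windows over a
# sequence of length n. If the full windows do not reach the end, one extra
# window is emitted whose true range is clipped at n (the amplitude sequence
# is right-padded with zeros to fill it).
conv_windows <- function(n, kernel, stride) {
  if (n >= kernel) {
    n_full <- (n - kernel) %/% stride + 1L
    starts <- (seq_len(n_full) - 1L) * stride
    ends <- starts + kernel
    if (ends[n_full] < n) {
      starts <- c(starts, n_full * stride)
      ends <- c(ends, n)
    }
  } else {
    starts <- 0L; ends <- n
  }
  cbind(start = as.integer(starts), end = as.integer(ends))
}

#' Tokenize a voxel signal and fuse with coordinate embeddings
#'
#' The raw voxel amplitude sequence at one time step is tokenized by a strided
#' 1D convolution; each token then receives, additively, the mean coordinate
#' embedding over the voxels in its receptive field (residual fusion at token
#' resolution). If the voxel count is not aligned to the kernel/stride the
#' sequence is right-padded with zeros to complete the final window; the
#' receptive map records the true, unpadded range.
#'
#' @param grid an [make_voxel_grid()] object carrying a `signal` matrix.
#' @param timestep 1-based row of `grid$signal` to tokenize.
#' @param conv a [conv1d_params()] list.
#' @param coord_params a [coord_embed_params()] list with matching `d`.
#' @param normalize_coords passed to [embed_coords()].
#' @return object of class `nf_tokenized` with `tokens` (`n_tok x d`),
#'   `receptive_map` (`n_tok x 2`, 0-based half-open voxel ranges), `d`,
#'   `n_vox`.
#' @export
tokenize_and_fuse <- function(grid, timestep = 1, conv, coord_params,
                              normalize_coords = TRUE) {
  validate_voxel_grid(grid)
  if (is.null(grid$signal)) nf_input_error("grid carries no signal")
  x <- grid$signal[timestep, ]
  tok <- tokenize_signal(x, conv)
  emb <- embed_coords(grid$coords, coord_params, normalize = normalize_coords)
  if (ncol(emb) != nrow(conv$W))
    nf_shape_error("conv output channels (%d) != coordinate embedding dim (%d)",
                   nrow(conv$W), ncol(emb))
  pooled <- pool_embedding(emb, tok$receptive_map)
  tok$tokens <- tok$tokens + pooled
  tok
}

# Convolution-only tokenization of a raw amplitude vector (no coordinates).
tokenize_signal <- function(x, conv) {
  n <- length(x)
  rmap <- conv_windows(n, conv$kernel, conv$stride)
  n_tok <- nrow(rmap)
  xp <- c(x, numeric(conv$kernel)) # right zero-pad for the remainder window
  Xw <- matrix(0, n_tok, conv$kernel)
  for (t in seq_len(n_tok)) {
    Xw[t, ] <- xp[(rmap[t, 1] + 1):(rmap[t, 1] + conv$kernel)]
  }
  tokens <- sweep(Xw %*% t(conv$W), 2, conv$b, "+")
  structure(list(tokens = tokens, receptive_map = rmap,
                 d = nrow(conv$W), n_vox = n),
            class = "nf_tokenized")
}

# Mean coordinate embedding over each token's true receptive range.
pool_embedding <- function(emb, rmap) {
  out <- matrix(0, nrow(rmap), ncol(emb))
  for (t in seq_len(nrow(rmap))) {
    out[t, ] <- colMeans(emb[(rmap[t, 1] + 1):rmap[t, 2], , drop = FALSE])
  }
  out
}

#' Pool a token sequence into per-ROI features
#'
#' Each ROI's feature is the weighted mean of the tokens, weighting every
#' token by the fraction of its receptive field that lies inside the ROI.
#'
#' @param tokenized an `nf_tokenized` object (or any list with `tokens` and a
#'   0-based half-open `receptive_map`).
#' @param grid the [make_voxel_grid()] the tokens were computed from.
#' @return `n_roi x d` matrix of per-ROI features.
#' @export
roi_pool <- function(tokenized, grid) {
  validate_voxel_grid(grid)
  W <- roi_overlap_fractions(tokenized$receptive_map, grid$roi_labels, grid$n_roi)
  tot <- rowSums(W)
  empty <- which(tot == 0)
  if (length(empty))
    nf_degenerate_error("ROI %d overlaps no token receptive field", empty[1] - 1L)
  (W / tot) %*% tokenized$tokens
}

# n_roi x n_tok matrix of receptive-field overlap fractions.
roi_overlap_fractions <- function(rmap, roi_labels, n_roi) {
  n_tok <- nrow(rmap)
  W <- matrix(0, n_roi, n_tok)
  for (t in seq_len(n_tok)) {
    lab <- roi_labels[(rmap[t, 1] + 1):rmap[t, 2]]
    frac <- tabulate(lab + 1L, nbins = n_roi) / length(lab)
    W[, t] <- frac
  }
  W
}
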