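# Coordinate embedding, whole-brain concatenation, 1D-conv tokenization with
# residual fusion, and receptive-field-weighted ROI pooling.

test_that("embed_coords is the affine image of the coordinates", {
  coords <- rbind(c(0, 0, 0), c(1, 2, 3), c(4, 0, 2), c(9, 9, 9), c(2, 5, 7))

  zero <- list(W = matrix(0, 3, 8), b = numeric(8))
  expect_equal(embed_coords(coords, zero), matrix(0, 5, 8))

  ident <- list(W = diag(3), b = numeric(3))
  expect_equal(embed_coords(coords, ident, normalize = FALSE),
               coords, ignore_attr = TRUE)

  set.seed(42)
  p <- list(W = matrix(rnorm(24), 3, 8), b = rnorm(8))
  got <- embed_coords(coords, p, normalize = FALSE)
  expected <- t(vapply(seq_len(5), function(i) {
    as.numeric(coords[i, ] %*% p$W + p$b) # brute-force per-voxel product
  }, numeric(8)))
  expect_equal(got, expected, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("embed_coords is translation-covariant without normalization", {
  set.seed(1)
  coords <- matrix(sample(0:20, 30, replace = TRUE), 10, 3)
  p <- list(W = matrix(rnorm(3 * 6), 3, 6), b = rnorm(6))
  t_shift <- c(2, -3, 5)
  e1 <- embed_coords(coords, p, normalize = FALSE)
  e2 <- embed_coords(sweep(coords, 2, t_shift, "+"), p, normalize = FALSE)
  shift <- as.numeric(t_shift %*% p$W)
  expect_equal(e2 - e1, matrix(shift, 10, 6, byrow = TRUE), tolerance = 1e-12)
})

test_that("concat_voxels preserves order and index arithmetic", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  expect_equal(concat_voxels(rbind(a)), a)
  expect_equal(concat_voxels(rbind(a, b)), c(a, b))
  expect_equal(concat_voxels(rbind(b, a)), c(b, a))
  expect_error(concat_voxels(list(a, c(1, 2))), class = "nf_shape_error")

  set.seed(2)
  M <- matrix(rnorm(28), 7, 4)
  v <- concat_voxels(M)
  expect_length(v, 28)
  for (i in 0:6) for (j in 0:3) {
    expect_identical(v[4 * i + j + 1], M[i + 1, j + 1])
  }
})

test_that("tokenizer arithmetic matches the sliding-window index oracle", {
  d <- 5
  g <- make_voxel_grid(64, 4, seed = 1)
  g$signal <- matrix(rnorm(64), 1)
  conv <- conv1d_params(d, kernel = 32, stride = 16, seed = 1)
  cp <- coord_embed_params(d, seed = 1)
  tok <- tokenize_and_fuse(g, 1, conv, cp)
  expect_equal(nrow(tok$tokens), 3)
  expect_equal(unname(tok$receptive_map),
               cbind(c(0L, 16L, 32L), c(32L, 48L, 64L)))

  # unaligned length: zero-padded remainder token with the true range recorded
  g2 <- make_voxel_grid(60, 4, seed = 1)
  g2$signal <- matrix(rnorm(60), 1)
  tok2 <- tokenize_and_fuse(g2, 1, conv, cp)
  expect_equal(unname(tok2$receptive_map),
               cbind(c(0L, 16L, 32L), c(32L, 48L, 60L)))
})

test_that("residual-only and conv-only limits recover each branch", {
  d <- 4
  g <- make_voxel_grid(64, 4, seed = 2)
  g$signal <- matrix(rnorm(64), 1)
  conv <- conv1d_params(d, kernel = 32, stride = 16, seed = 1)
  cp <- coord_embed_params(d, seed = 1)

  conv0 <- conv; conv0$W[] <- 0; conv0$b[] <- 0
  tok <- tokenize_and_fuse(g, 1, conv0, cp)
  emb <- embed_coords(g$coords, cp)
  pooled <- rbind(colMeans(emb[1:32, ]), colMeans(emb[17:48, ]),
                  colMeans(emb[33:64, ]))
  expect_equal(tok$tokens, pooled, tolerance = 1e-12)

  cp0 <- cp; cp0$W[] <- 0; cp0$b[] <- 0
  tok2 <- tokenize_and_fuse(g, 1, conv, cp0)
  x <- g$signal[1, ]
  manual <- t(vapply(c(0, 16, 32), function(s) {
    as.numeric(conv$W %*% x[(s + 1):(s + 32)] + conv$b)
  }, numeric(d)))
  expect_equal(tok2$tokens, manual, tolerance = 1e-12)
})

test_that("kernel-1 stride-1 tokenization degenerates to per-voxel fusion", {
  d <- 3
  g <- make_voxel_grid(10, 2, seed = 3)
  g$signal <- matrix(rnorm(10), 1)
  conv <- conv1d_params(d, kernel = 1, stride = 1, seed = 2)
  cp <- coord_embed_params(d, seed = 2)
  tok <- tokenize_and_fuse(g, 1, conv, cp)
  emb <- embed_coords(g$coords, cp)
  expected <- outer(g$signal[1, ], as.numeric(conv$W)) + emb
  expect_equal(tok$tokens, expected, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("roi_pool computes receptive-field-weighted means", {
  tokens <- rbind(c(1, 10), c(2, 20), c(3, 30))
  rmap <- cbind(c(0L, 2L, 4L), c(4L, 6L, 6L))
  coords <- cbind(0:5, 0L, 0L)

  one_roi <- random_grid_with_labels(coords, rep(0L, 6))
  expect_equal(roi_pool(list(tokens = tokens, receptive_map = rmap), one_roi),
               rbind(colMeans(tokens)), ignore_attr = TRUE)

  const <- matrix(rep(c(7, -1), each = 3), 3)
  two_roi <- random_grid_with_labels(coords, c(0L, 0L, 1L, 1L, 1L, 1L))
  got <- roi_pool(list(tokens = const, receptive_map = rmap), two_roi)
  expect_equal(got, matrix(rep(c(7, -1), each = 2), 2), ignore_attr = TRUE)

  # hand-computed overlap fractions:
  # token1 covers voxels 0-3: ROI0 2/4, ROI1 2/4
  # token2 covers voxels 2-5: ROI1 4/4; token3 covers 4-5: ROI1 2/2
  got2 <- roi_pool(list(tokens = tokens, receptive_map = rmap), two_roi)
  expect_equal(got2[1, ], tokens[1, ], tolerance = 1e-6)
  w <- c(0.5, 1, 1)
  expect_equal(got2[2, ], colSums(tokens * w) / sum(w), tolerance = 1e-6)
})

test_that("degenerate grids are rejected with the ROI named", {
  coords <- cbind(0:3, 0L, 0L)
  g <- random_grid_with_labels(coords, c(0L, 0L, 2L, 2L))
  g$n_roi <- 3L
  expect_error(
    roi_pool(list(tokens = matrix(1, 2, 2),
                  receptive_map = cbind(c(0L, 2L), c(2L, 4L))), g),
    "ROI 1", class = "nf_degenerate_error")
})
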