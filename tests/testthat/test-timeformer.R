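# Sliced-window transformer: window coverage, masking, residual limits,
# overlap-average reassembly, determinism and the windowed-attention cost.

test_that("window_starts matches the stated slicing examples", {
  expect_equal(unname(window_starts(64, 64, 32)), cbind(0L, 64L))

  st <- window_starts(128, 64, 32)
  expect_equal(st[, "start"], c(0L, 32L, 64L), ignore_attr = TRUE)
  expect_equal(st[, "true_len"], rep(64L, 3), ignore_attr = TRUE)

  st2 <- window_starts(70, 64, 32, "pad_last")
  expect_equal(unname(st2), cbind(c(0L, 32L), c(64L, 38L)))

  expect_warning(st3 <- window_starts(70, 64, 32, "drop_last"),
                 "6 token")
  expect_equal(nrow(st3), 1)

  expect_error(window_starts(0, 4, 2), class = "nf_degenerate_error")
})

test_that("pad_last covers every index on a sampled config grid", {
  set.seed(1)
  for (rep in 1:200) {
    L <- sample(1:256, 1); w <- sample(1:64, 1); s <- sample(1:w, 1)
    st <- window_starts(L, w, s)
    covered <- logical(L)
    for (i in seq_len(nrow(st))) {
      covered[(st[i, 1] + 1):(st[i, 1] + st[i, 2])] <- TRUE
    }
    expect_true(all(covered))
    n_full <- if (L >= w) (L - w) %/% s + 1L else 0L
    expect_true(nrow(st) %in% c(n_full, n_full + 1L))
  }
})

test_that("slice_windows extracts and zero-pads contents correctly", {
  set.seed(2)
  X <- matrix(rnorm(70 * 3), 70, 3)
  sl <- slice_windows(X, list(w = 64, s = 32, pad_policy = "pad_last"))
  expect_length(sl, 2)
  expect_equal(sl[[1]]$content, X[1:64, ])
  expect_equal(sl[[2]]$content[1:38, ], X[33:70, ])
  expect_equal(sl[[2]]$content[39:64, ], matrix(0, 26, 3))
  expect_equal(sl[[2]]$start, 32L)
  expect_equal(sl[[2]]$true_len, 38L)
})

test_that("padded keys receive zero attention mass from real positions", {
  p <- trans_block_params(8, n_heads = 2, seed = 3)
  sl <- list(content = rbind(matrix(rnorm(3 * 8), 3, 8), matrix(0, 5, 8)),
             true_len = 3)
  A <- neurofusion:::attention_weights(sl, p)
  expect_equal(rowSums(A[1:3, 4:8, drop = FALSE]), rep(0, 3))
  expect_equal(rowSums(A[1:3, 1:3, drop = FALSE]), rep(1, 3))
})

test_that("zeroed residual branches make trans_block the identity", {
  p <- identity_block(trans_block_params(8, n_heads = 2, seed = 4))
  sl <- list(content = matrix(rnorm(6 * 8), 6, 8), true_len = 6)
  out <- trans_block(sl, p)
  expect_equal(out$content, sl$content, tolerance = 1e-12)
})

test_that("masked computation equals truncated computation", {
  d <- 8
  p <- trans_block_params(d, n_heads = 2, seed = 5)
  x <- rnorm(d)
  wide <- trans_block(list(content = rbind(x, matrix(0, 7, d)), true_len = 1), p)
  narrow <- trans_block(list(content = rbind(x), true_len = 1), p)
  expect_equal(wide$content[1, ], narrow$content[1, ], tolerance = 1e-5)
})

test_that("degenerate composition: identity blocks give the token mean", {
  cfg <- timeformer_config(w = 16, s = 8, h = 1, d = 8, n_heads = 2)
  params <- timeformer_params(cfg, seed = 6)
  params$layers[[1]] <- identity_block(params$layers[[1]])
  X <- matrix(rnorm(16 * 8), 16, 8)
  ff <- timeformer_forward(X, cfg, params)
  expect_equal(ff$global, colMeans(X), tolerance = 1e-12)
  expect_equal(ff$tokens, X, tolerance = 1e-12)
})

test_that("overlap reassembly averages window outputs position-wise", {
  d <- 8
  cfg <- timeformer_config(w = 64, s = 32, h = 1, d = d, n_heads = 2)
  params <- timeformer_params(cfg, seed = 7)
  X <- matrix(rnorm(96 * d), 96, d)
  ff <- timeformer_forward(X, cfg, params)

  # explicit oracle: slice by hand, transform, average overlaps
  blocks <- lapply(c(0, 32), function(s0) {
    trans_block(list(content = X[(s0 + 1):(s0 + 64), ], true_len = 64),
                params$layers[[1]])$content
  })
  # position 40 (0-based) lies in windows starting at 0 and 32
  expected_40 <- (blocks[[1]][41, ] + blocks[[2]][9, ]) / 2
  expect_equal(ff$tokens[41, ], expected_40, tolerance = 1e-10)
  # position 10 lies only in the first window
  expect_equal(ff$tokens[11, ], blocks[[1]][11, ], tolerance = 1e-10)
})

test_that("forward pass is deterministic and batch-independent", {
  cfg <- timeformer_config(w = 8, s = 4, h = 2, d = 8, n_heads = 2)
  params <- timeformer_params(cfg, seed = 8)
  X <- matrix(rnorm(20 * 8), 20, 8)
  expect_identical(timeformer_forward(X, cfg, params),
                   timeformer_forward(X, cfg, params))

  # permuting samples permutes fMRI-branch outputs identically
  p <- generate_pairs(tiny_cfg(n_samples = 5, img_size = 16))
  m <- tiny_model()
  fm <- fmri_encode(m, p$grid, p$responses)
  perm <- c(3, 1, 5, 2, 4)
  fm2 <- fmri_encode(m, p$grid, p$responses[perm, ])
  expect_equal(fm2$global, fm$global[perm, ], tolerance = 1e-12)
  expect_equal(fm2$per_roi, fm$per_roi[perm, , ], tolerance = 1e-12)
})

test_that("attention cost is n_windows * w^2 and beats full attention", {
  for (L in c(65, 128, 200, 256)) {
    st <- window_starts(L, 64, 32)
    expect_equal(attention_pair_count(L, 64, 32), nrow(st) * 64^2)
  }
  # the windowed cost undercuts full L^2 attention once L >= 2w
  for (L in c(128, 200, 256)) {
    expect_lt(attention_pair_count(L, 64, 32), L^2)
  }
})

test_that("the window/stride ablation grid constructs and runs", {
  X <- matrix(rnorm(200 * 16), 200, 16)
  for (ws in list(c(128, 64), c(128, 32), c(64, 32))) {
    cfg <- timeformer_config(w = ws[1], s = ws[2], h = 2, d = 16, n_heads = 4)
    ff <- timeformer_forward(X, cfg, timeformer_params(cfg, seed = 9))
    expect_true(all(is.finite(ff$global)))
    expect_equal(dim(ff$tokens), dim(X))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(timeformer_config(w = 8, s = 16), class = "nf_config_error")
  expect_error(timeformer_config(d = 10, n_heads = 4), class = "nf_config_error")
  expect_error(timeformer_config(h = 0), class = "nf_config_error")
})
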