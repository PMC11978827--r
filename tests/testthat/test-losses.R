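# Contrastive and ROI-guided losses against closed forms and the brute-force
# loop oracles (helper-oracles.R), plus the fusion block contracts.

test_that("contrastive loss closed forms hold", {
  set.seed(1)
  p <- matrix(rnorm(8), 1)
  expect_equal(contrastive_loss(p, matrix(rnorm(8), 1)), 0, tolerance = 1e-12)

  # uniform similarities: identical rows
  P <- matrix(rep(rnorm(8), each = 4), 4)
  expect_equal(contrastive_loss(P, P, sigma = 0.07), 2 * log(4),
               tolerance = 1e-9)

  # temperature limit sigma -> Inf flattens the softmax
  P2 <- matrix(rnorm(6 * 8), 6); Q2 <- matrix(rnorm(6 * 8), 6)
  expect_equal(contrastive_loss(P2, Q2, sigma = 1e6), 2 * log(6),
               tolerance = 1e-3)

  # near-one-hot similarities drive the loss to ~0
  I6 <- diag(6)
  expect_lt(contrastive_loss(I6, I6, sigma = 0.01), 1e-6)
  expect_gte(contrastive_loss(P2, Q2, sigma = 0.07), 0)
})

test_that("contrastive loss matches the double-loop oracle", {
  set.seed(2)
  for (trial in 1:10) {
    n <- sample(2:8, 1); d <- sample(2:16, 1)
    P <- matrix(rnorm(n * d), n); Q <- matrix(rnorm(n * d), n)
    sigma <- runif(1, 0.05, 1)
    expect_equal(contrastive_loss(P, Q, sigma),
                 lcon_oracle(P, Q, sigma), tolerance = 1e-6)
    expect_equal(contrastive_loss(P, Q, sigma, normalize = FALSE),
                 lcon_oracle(P, Q, sigma, normalize = FALSE),
                 tolerance = 1e-6)
  }
})

test_that("contrastive loss is symmetric and permutation-invariant", {
  set.seed(3)
  P <- matrix(rnorm(5 * 8), 5); Q <- matrix(rnorm(5 * 8), 5)
  expect_equal(contrastive_loss(P, Q, 0.2), contrastive_loss(Q, P, 0.2),
               tolerance = 1e-12)
  perm <- sample(5)
  expect_equal(contrastive_loss(P[perm, ], Q[perm, ], 0.2),
               contrastive_loss(P, Q, 0.2), tolerance = 1e-12)
})

test_that("ROI-guided loss closed forms hold", {
  expect_equal(fmri_guided_loss(array(rnorm(4), c(1, 1, 4)),
                                array(rnorm(4), c(1, 1, 4))), 0,
               tolerance = 1e-12)

  # uniform similarities: every ROI feature identical
  v <- rnorm(8)
  Pl <- array(rep(v, each = 2 * 6), c(2, 6, 8))
  expect_equal(fmri_guided_loss(Pl, Pl), 2 * log(6), tolerance = 1e-9)
  expect_equal(fmri_guided_loss(Pl, Pl, batch_norm = TRUE), log(6),
               tolerance = 1e-9)
})

test_that("ROI-guided loss matches the triple-loop oracle", {
  set.seed(4)
  for (trial in 1:10) {
    n <- sample(1:4, 1); nr <- sample(2:6, 1); d <- sample(2:8, 1)
    Pl <- array(rnorm(n * nr * d), c(n, nr, d))
    Qr <- array(rnorm(n * nr * d), c(n, nr, d))
    expect_equal(fmri_guided_loss(Pl, Qr), lbfg_oracle(Pl, Qr),
                 tolerance = 1e-6)
    expect_equal(fmri_guided_loss(Pl, Qr, normalize = FALSE),
                 lbfg_oracle(Pl, Qr, normalize = FALSE), tolerance = 1e-6)
  }
})

test_that("total loss is the exact weighted sum", {
  expect_equal(total_loss(1.5, 0.4, loss_config(lambda_con = 0, lambda_bfg = 0)), 0)
  expect_equal(total_loss(1.5, 0.4, loss_config(lambda_con = 1, lambda_bfg = 0)), 1.5)
  expect_equal(total_loss(1.5, 0.4, loss_config(lambda_con = 0.7, lambda_bfg = 2)),
               0.7 * 1.5 + 2 * 0.4, tolerance = 1e-12)
  expect_error(loss_config(lambda_con = -1), class = "nf_config_error")
  expect_error(loss_config(sigma = 0), class = "nf_config_error")
  expect_error(total_loss(NaN, 0, loss_config()), class = "nf_numeric_error")
})

test_that("shape violations are rejected", {
  expect_error(contrastive_loss(matrix(0, 2, 3), matrix(0, 3, 3)),
               class = "nf_shape_error")
  expect_error(fmri_guided_loss(array(0, c(2, 3, 4)), array(0, c(2, 2, 4))),
               class = "nf_shape_error")
  expect_error(contrastive_loss(matrix(NaN, 2, 2), matrix(0, 2, 2)),
               class = "nf_numeric_error")
})

test_that("fusion assembles 2 + 2*N_r tokens and honours the residual limit", {
  d <- 8; nr <- 6; n <- 2
  set.seed(5)
  vis <- list(global = matrix(rnorm(n * d), n),
              local = array(rnorm(n * nr * d), c(n, nr, d)))
  fm <- list(global = matrix(rnorm(n * d), n),
             per_roi = array(rnorm(n * nr * d), c(n, nr, d)))
  fp <- fuse_params(d, nr, n_heads = 2, seed = 6)
  out <- fuse(vis, fm, fp)
  expect_equal(dim(out$tokens), c(n, 14, d))
  expect_equal(dim(out$pooled), c(n, d))

  fp0 <- fp
  fp0$block <- identity_block(fp0$block)
  out0 <- fuse(vis, fm, fp0)
  expected1 <- colMeans(rbind(
    vis$global[1, ] + fp$types[1, ], fm$global[1, ] + fp$types[2, ],
    sweep(matrix(vis$local[1, , ], nr), 2, fp$types[3, ], "+"),
    sweep(matrix(fm$per_roi[1, , ], nr), 2, fp$types[4, ], "+")))
  expect_equal(out0$pooled[1, ], expected1, tolerance = 1e-12)
})

test_that("swapping modalities with symmetric type embeddings permutes tokens", {
  d <- 8; nr <- 3; n <- 1
  set.seed(7)
  vis <- list(global = matrix(rnorm(d), 1),
              local = array(rnorm(nr * d), c(1, nr, d)))
  fm <- list(global = matrix(rnorm(d), 1),
             per_roi = array(rnorm(nr * d), c(1, nr, d)))
  fp <- fuse_params(d, nr, n_heads = 2, seed = 8, symmetric_types = TRUE)
  a <- fuse(vis, fm, fp)
  b <- fuse(list(global = fm$global, local = fm$per_roi),
            list(global = vis$global, per_roi = vis$local), fp)
  perm <- c(2, 1, (2 + nr + 1):(2 + 2 * nr), 3:(2 + nr))
  expect_equal(b$tokens[1, perm, ], a$tokens[1, , ], tolerance = 1e-10)
  expect_equal(b$pooled, a$pooled, tolerance = 1e-10)
})
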