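# Head training: frozen-optimizer and determinism contracts, analytic
# gradients against central finite differences, and training dynamics on a
# small coupled dataset.

local_tiny_training <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- generate_pairs(tiny_cfg(n_samples = 24, seed = 5,
                                   alignment_strength = 0.9, noise_sd = 0.1))
      m <- tiny_model(seed = 2)
      f <- precompute_features(m, p)
      cache <<- list(p = p, m = m, f = f)
    }
    cache
  }
})

test_that("lr = 0 freezes parameters and the loss history", {
  tt <- local_tiny_training()
  # full-batch so the frozen loss is computed on the same set every epoch
  cfg <- train_config(lr = 0, epochs = 3, batch_size = 24, seed = 1,
                      holdout_frac = 0)
  tr <- train(tt$p, tt$m, cfg, features = tt$f)
  expect_identical(neurofusion:::get_theta(tr$model),
                   neurofusion:::get_theta(tt$m))
  expect_equal(tr$history$total, rep(tr$history$total[1], 3))
})

test_that("training is deterministic given the seed", {
  tt <- local_tiny_training()
  cfg <- train_config(lr = 0.01, epochs = 2, batch_size = 8, seed = 9)
  t1 <- train(tt$p, tt$m, cfg, features = tt$f)
  t2 <- train(tt$p, tt$m, cfg, features = tt$f)
  expect_identical(t1$history, t2$history)
  expect_identical(neurofusion:::get_theta(t1$model),
                   neurofusion:::get_theta(t2$model))
})

test_that("analytic gradients match central finite differences", {
  tt <- local_tiny_training()
  f8 <- neurofusion:::subset_features(tt$f, 1:8)
  lc <- loss_config()
  lg <- neurofusion:::loss_and_grads(tt$m, f8, lc, 0.1)
  theta <- neurofusion:::get_theta(tt$m)
  eps <- 1e-5
  for (nm in c("W_g", "q_W", "W_l2", "roi_W", "b_g", "roi_b", "enc_W", "enc_b")) {
    g <- lg$grads[[nm]]
    pick <- function(x) if (is.matrix(x)) x[2, 1] else x[2]
    poke <- function(x, e) { if (is.matrix(x)) x[2, 1] <- x[2, 1] + e else x[2] <- x[2] + e; x }
    vals <- vapply(c(-eps, eps), function(e) {
      th <- theta; th[[nm]] <- poke(th[[nm]], e)
      o <- neurofusion:::loss_and_grads(neurofusion:::set_theta(tt$m, th),
                                        f8, lc, 0.1, want_grads = FALSE)
      # the encoding head trains on the MSE term; all other heads train on
      # the contrastive + ROI-guided total (MSE is stop-gradiented into them)
      if (nm %in% c("enc_W", "enc_b")) 0.1 * o$mse else o$total
    }, numeric(1))
    num <- (vals[2] - vals[1]) / (2 * eps)
    expect_equal(pick(g), num, tolerance = 1e-4,
                 label = sprintf("analytic gradient of %s", nm))
  }
})

test_that("training reduces the objective and improves matched similarity", {
  tt <- local_tiny_training()
  cfg <- train_config(lr = 0.01, epochs = 10, batch_size = 8, seed = 3,
                      holdout_frac = 0)
  score0 <- roi_alignment_score(tt$m, tt$f)
  sf0 <- shared_features(tt$m, tt$f)
  gap0 <- mean(diag(tcrossprod(sf0$P, sf0$Q))) -
    mean(tcrossprod(sf0$P, sf0$Q)[row(diag(24)) != col(diag(24))])
  tr <- train(tt$p, tt$m, cfg, features = tt$f)
  expect_lt(tr$history$total[10], tr$history$total[1])
  expect_lt(tr$history$l_con[10], tr$history$l_con[1])

  # gradient direction: matched-pair similarity pulls ahead of mismatched
  sf1 <- shared_features(tr$model, tt$f)
  gap1 <- mean(diag(tcrossprod(sf1$P, sf1$Q))) -
    mean(tcrossprod(sf1$P, sf1$Q)[row(diag(24)) != col(diag(24))])
  expect_gt(gap1, gap0)
  expect_gt(roi_alignment_score(tr$model, tt$f), score0)
})

test_that("non-finite losses abort with the batch named", {
  tt <- local_tiny_training()
  f_bad <- tt$f
  f_bad$fmri_global[1, 1] <- NaN
  cfg <- train_config(lr = 0.01, epochs = 1, batch_size = 24, seed = 1,
                      holdout_frac = 0)
  expect_error(train(tt$p, tt$m, cfg, features = f_bad),
               "epoch 1, batch 1", class = "nf_numeric_error")
})

test_that("train config validation rejects bad values", {
  expect_error(train_config(lr = -1), class = "nf_config_error")
  expect_error(train_config(epochs = 1.5), class = "nf_config_error")
  expect_error(train_config(holdout_frac = 1), class = "nf_config_error")
})

test_that("evaluate reports bounded metrics on the held-out split", {
  tt <- local_tiny_training()
  cfg <- train_config(lr = 0.01, epochs = 3, batch_size = 8, seed = 4,
                      holdout_frac = 0.25)
  tr <- train(tt$p, tt$m, cfg, features = tt$f)
  ev <- evaluate(tr)
  expect_equal(ev$n_test, 6)
  expect_gte(ev$retrieval_top1, 0); expect_lte(ev$retrieval_top1, 1)
  expect_gte(ev$retrieval_top5, ev$retrieval_top1)
  expect_gte(ev$mean_pcc, -1); expect_lte(ev$mean_pcc, 1)
})
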