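test_that("residual blocks reduce to the skip path when F is zeroed", {
  w <- residual_block_weights(4, 4, k = 3, seed = 1)
  x <- matrix(rnorm(40), 10, 4)
  w0 <- w
  w0$conv1$W[] <- 0; w0$conv1$b[] <- 0
  w0$conv2$W[] <- 0; w0$conv2$b[] <- 0
  expect_equal(residual_block(x, w0), x)            # Y = 0 + x
  y <- residual_block(x, w)
  expect_equal(dim(y), dim(x))                      # shape preserved
  # projection path when channel counts differ
  wp <- residual_block_weights(4, 6, k = 3, seed = 2)
  expect_equal(dim(residual_block(x, wp)), c(10L, 6L))
})

test_that("gradients flow through the skip path when F is zeroed", {
  pf <- asNamespace("promoforge")
  set.seed(3)
  layer <- pf$nn_resblock(3L, 3L, 3L)
  layer$params$conv1$W[] <- 0
  layer$params$conv2$W[] <- 0
  M <- matrix(rnorm(9), 3, 3)   # one sample, three positions
  fw <- pf$net_forward(list(layer), M, 1L, 3L)
  bw <- pf$net_backward(list(layer), fw, 2 * fw$st$M)
  # analytic input gradient vs central differences on sum-of-squares
  eps <- 1e-6
  for (idx in seq_along(M)) {
    M2 <- M; M2[idx] <- M[idx] + eps
    lp <- sum(pf$net_forward(list(layer), M2, 1L, 3L)$st$M^2)
    M2[idx] <- M[idx] - eps
    lm_ <- sum(pf$net_forward(list(layer), M2, 1L, 3L)$st$M^2)
    expect_equal(bw$dx[idx], (lp - lm_) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("self-attention matches its defining softmax form", {
  # single position: softmax over one logit is 1, output equals V
  Q <- matrix(rnorm(4), 1); K <- matrix(rnorm(4), 1); V <- matrix(rnorm(4), 1)
  expect_equal(self_attention(Q, K, V), V)
  # orthogonal Q/K (all logits equal): output is the column mean of V
  Qo <- matrix(0, 3, 2)
  Ko <- matrix(rnorm(8), 4, 2)
  Vo <- matrix(rnorm(12), 4, 3)
  out <- self_attention(Qo, Ko, Vo)
  expect_equal(out, matrix(colMeans(Vo), 3, 3, byrow = TRUE))
  # attention rows are probability distributions
  r <- self_attention(matrix(rnorm(10), 5), matrix(rnorm(14), 7),
                      matrix(rnorm(21), 7), return_weights = TRUE)
  expect_equal(unname(rowSums(r$weights)), rep(1, 5), tolerance = 1e-6)
  expect_error(self_attention(Qo, Ko, Vo, d_k = 0), "positive")
  expect_error(self_attention(Qo, Ko[, 1, drop = FALSE], Vo), "dimension")
})

test_that("built networks have the declared structure and seeded init", {
  cfg <- net_config(arch = "resnet_attention", task = "binary",
                    n_resblocks = 20, channels = 6, seed = 9)
  m <- build_network(cfg, c(50, 4))
  expect_equal(sum(vapply(m$layers, function(l) l$type == "resblock",
                          logical(1))), 20L)
  X <- one_hot_encode(rand_dna(8, 50, seed = 1))
  p <- predict(m, X)
  expect_true(all(p > 0 & p < 1))           # sigmoid range
  m2 <- build_network(cfg, c(50, 4))
  expect_identical(promoforge:::params_of(m$layers),
                   promoforge:::params_of(m2$layers))
  expect_error(net_config(arch = "mlp"), "arg")
})

test_that("training is seeded, epoch-countable, and learns separable data", {
  ds <- simulate_real_fake(
    synthetic_spec(n = 200, minus35_pwm = consensus_pwm("TTGACA", 1),
                   minus10_pwm = consensus_pwm("TATAAT", 1), seed = 31),
    "background")
  y <- as.integer(ds$realness_label == "real")
  X <- one_hot_encode(ds$sequence)
  cfg <- net_config(arch = "simple_cnn", task = "binary", channels = 12,
                    epochs = 20, learning_rate = 3e-3, batch_size = 32,
                    seed = 7)
  m <- build_network(cfg, c(50, 4))
  m0 <- train_supervised(m, X, y, modifyList(cfg, list(epochs = 0L)))
  expect_identical(m0$history, numeric(0))  # epochs = 0 is the identity
  mt <- train_supervised(m, X, y, cfg)
  expect_length(mt$history, 20L)
  expect_gte(mean((predict(mt, X) > 0.5) == y), 0.95)
  mt2 <- train_supervised(build_network(cfg, c(50, 4)), X, y, cfg)
  expect_identical(mt$history, mt2$history)
  expect_error(train_supervised(m, X, c(y[-1], NA), cfg), "NA")
  expect_warning(train_supervised(m, X, rep(1, length(y)),
                                  modifyList(cfg, list(epochs = 1L))),
                 "single-class")
})

test_that("prediction is pure and per-sample independent", {
  cfg <- net_config(arch = "simple_cnn", task = "regression", channels = 6,
                    epochs = 2, seed = 3, dropout_rate = 0.5)
  X <- one_hot_encode(rand_dna(10, 50, seed = 2))
  m <- train_supervised(build_network(cfg, c(50, 4)), X, rnorm(10), cfg)
  p1 <- predict(m, X)
  p2 <- predict(m, X)
  expect_identical(p1, p2)                  # dropout off at predict time
  perm <- sample(10)
  expect_equal(predict(m, promoforge:::keep_feat_attrs(
    unclass(X)[perm, ], X)), p1[perm])
  expect_error(predict(m, one_hot_encode(rand_dna(3, 40))), "match")
})

test_that("cross-validation partitions data and is honest on null labels", {
  ds <- simulate_real_fake(synthetic_spec(n = 80, seed = 41), "background")
  # destroy the signal: random labels
  set.seed(5)
  ds$realness_label <- sample(ds$realness_label)
  cfg <- net_config(arch = "simple_cnn", task = "binary", channels = 4,
                    epochs = 5, batch_size = 16, seed = 11)
  accs <- vapply(1:5, function(r) {
    rep_r <- cross_validate(cfg, ds, k = 4, seed = r, target = "realness")
    expect_equal(sort(unlist(lapply(1:4, function(f)
      which(rep_r$folds == f)))), seq_len(nrow(ds)))   # disjoint cover
    rep_r$mean_Acc
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
  expect_error(cross_validate(cfg, ds, k = 100, seed = 1), "folds")
})

test_that("grid search is exhaustive with deterministic tie-breaks", {
  ds <- simulate_real_fake(
    synthetic_spec(n = 60, minus35_pwm = consensus_pwm("TTGACA", 1),
                   minus10_pwm = consensus_pwm("TATAAT", 1), seed = 51),
    "background")
  cfg <- net_config(arch = "simple_cnn", task = "binary", channels = 4,
                    epochs = 3, seed = 2)
  out <- hyperparameter_search(cfg, ds, learning_rates = c(1e-3, 1e-2),
                               batch_sizes = c(8, 32), k = 2, seed = 4)
  expect_equal(nrow(out$report), 4L)        # one row per grid point
  best_score <- out$report$score[
    out$report$learning_rate == out$best_config$learning_rate &
      out$report$batch_size == out$best_config$batch_size]
  expect_true(all(best_score >= out$report$score))
  single <- hyperparameter_search(cfg, ds, 5e-3, 16, k = 2, seed = 4)
  expect_equal(single$best_config$learning_rate, 5e-3)
  expect_equal(single$best_config$batch_size, 16L)
  expect_error(hyperparameter_search(cfg, ds, numeric(0), 16), "empty")
})

test_that("classical baselines recover linear signal and reject noise", {
  set.seed(6)
  X <- promoforge:::new_feature_matrix(matrix(rnorm(200 * 12), 200), "onehot")
  beta <- rnorm(12)
  y_lin <- as.vector(unclass(X) %*% beta)
  expect_gte(baseline_ml(X, y_lin, "elastic_net", k = 5, seed = 1)$mean_PCC,
             0.95)
  y_noise <- rnorm(200)
  expect_lt(abs(baseline_ml(X, y_noise, "elastic_net", k = 5,
                            seed = 1)$mean_PCC), 0.2)
  g1 <- baseline_ml(X, y_lin, "gradient_boosted_trees", k = 3, seed = 2)
  g2 <- baseline_ml(X, y_lin, "gradient_boosted_trees", k = 3, seed = 2)
  expect_identical(g1$per_fold, g2$per_fold)
  expect_gt(g1$mean_PCC, 0.5)
})

test_that("model checkpoints round-trip through the save container", {
  cfg <- net_config(arch = "simple_cnn", task = "binary", channels = 4,
                    epochs = 2, seed = 13)
  X <- one_hot_encode(rand_dna(20, 50, seed = 3))
  y <- rep(0:1, 10)
  m <- train_supervised(build_network(cfg, c(50, 4)), X, y, cfg)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_equal(predict(m2, X), predict(m, X))
  expect_equal(m2$history, m$history)
})
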