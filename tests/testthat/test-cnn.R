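test_that("architecture shape contract holds across input lengths", {
  set.seed(21)
  for (len in c(8, 17, 40, 97, 256)) {
    # independent oracle: three repeated floor divisions by the pool size
    L <- len
    for (i in 1:3) L <- L %/% 2
    if (L < 1) next
    cfg <- cnn_config(input_length = len, n_classes = 3,
                      conv_channels = c(4, 8, 16), dense_sizes = c(8),
                      dropout_rates = c(0.2))
    model <- build_cnn(cfg, init_seed = 5)
    model <- train_cnn(model, matrix(rnorm(6 * len), 6, len),
                       factor(rep(letters[1:3], 2)),
                       train_config(epochs = 1, batch_size = 2, seed = 1))
    fmg <- extract_feature_map_gradients(model, rnorm(len), 1)
    expect_equal(dim(fmg$activations), c(16, L))
    expect_equal(dim(fmg$gradients), c(16, L))
    logits <- predict(model, matrix(rnorm(2 * len), 2, len), type = "logit")
    expect_equal(dim(logits), c(2, 3))
    expect_true(all(is.finite(logits)))
  }
})

test_that("default architecture matches the reference layer arithmetic", {
  cfg <- cnn_config()
  expect_equal(cfg$conv_channels, c(64L, 128L, 256L))
  expect_equal(cfg$block_lengths, c(3074L, 1537L, 768L))
  expect_equal(cfg$flatten_size, 196608L)
  expect_equal(cfg$n_classes, 4L)
  expect_error(cnn_config(input_length = 7), "too short")
})

test_that("default training protocol echoes the reference settings", {
  tc <- train_config()
  expect_equal(tc$epochs, 50L)
  expect_equal(tc$learning_rate, 1e-4)
  expect_equal(tc$batch_size, 32L)
})

test_that("training reduces the loss and is seed-reproducible", {
  fix <- tiny_cnn()
  loss <- fix$model$loss_history
  expect_lt(tail(loss, 1), loss[1])
  expect_gt(mean(predict(fix$model, fix$X) == fix$y), 0.9)
  # identical seed -> identical weights
  cfg <- fix$model$config
  m1 <- build_cnn(cfg, init_seed = 11)
  m2 <- build_cnn(cfg, init_seed = 11)
  tc <- train_config(epochs = 3, learning_rate = 1e-3, batch_size = 8,
                     seed = 3)
  m1 <- train_cnn(m1, fix$X, fix$y, tc)
  m2 <- train_cnn(m2, fix$X, fix$y, tc)
  expect_identical(m1$conv[[1]]$W, m2$conv[[1]]$W)
  expect_identical(m1$out$W, m2$out$W)
  expect_identical(m1$loss_history, m2$loss_history)
})

test_that("inference is deterministic (dropout off, running statistics)", {
  fix <- tiny_cnn()
  l1 <- predict(fix$model, fix$X[1:5, ], type = "logit")
  l2 <- predict(fix$model, fix$X[1:5, ], type = "logit")
  expect_identical(l1, l2)
  p <- predict(fix$model, fix$X[1:5, ], type = "prob")
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
})

test_that("training rejects mismatched shapes and untrained prediction", {
  cfg <- cnn_config(input_length = 32, n_classes = 2,
                    conv_channels = c(4, 4, 4), dense_sizes = c(8),
                    dropout_rates = c(0))
  m <- build_cnn(cfg)
  expect_error(predict(m, matrix(0, 1, 32)), "trained")
  expect_error(train_cnn(m, matrix(0, 4, 31), factor(c(1, 2, 1, 2)),
                         train_config(epochs = 1)), "columns")
  expect_error(train_cnn(m, matrix(0, 4, 32), factor(1:4),
                         train_config(epochs = 1)), "n_classes")
})
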