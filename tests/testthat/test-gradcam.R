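fake_fmg <- function(A, g) {
  structure(list(activations = A, gradients = g, class_index = 1L,
                 class_score = 0, input_length = ncol(A) * 2L),
            class = "feature_map_gradients")
}

test_that("alpha weights follow the closed-form reformulation", {
  # single map, single location: g = 1, A = 1 -> alpha = 1/3
  expect_equal(compute_alpha_weights(fake_fmg(matrix(1), matrix(1)))[1, 1],
               1 / 3)
  # A = 0 removes the third-derivative sum -> alpha = 1/2
  expect_equal(compute_alpha_weights(fake_fmg(matrix(0), matrix(1)))[1, 1],
               1 / 2)
  # degenerate denominator guard
  expect_equal(compute_alpha_weights(fake_fmg(matrix(1), matrix(0)))[1, 1],
               0)
  # two locations in one map share the third-derivative sum
  A <- matrix(c(1, 2), 1)
  g <- matrix(c(1, 1), 1)
  al <- compute_alpha_weights(fake_fmg(A, g))
  expect_equal(al[1, 1], 1 / (2 + 3))
  expect_equal(al[1, 2], 1 / (2 + 3))
})

test_that("negative gradients annihilate the map; CAM stays non-negative", {
  A <- matrix(runif(12), 3)
  g <- -matrix(runif(12), 3)
  fmg <- fake_fmg(A, g)
  cam <- compute_cam(fmg, compute_alpha_weights(fmg))
  expect_true(all(cam$raw == 0))
  expect_true(all(cam$upsampled == 0))
  # single map with w = 1: CAM is the ReLU of the map
  fmg2 <- fake_fmg(matrix(c(1, -2, 3), 1), matrix(c(1, 0, 0), 1))
  alpha <- matrix(c(1, 0, 0), 1)   # gives w = 1
  cam2 <- compute_cam(fmg2, alpha)
  expect_equal(cam2$raw, c(1, 0, 3))
  expect_true(all(cam2$upsampled >= 0))
})

test_that("feature-map gradients match finite differences of the score", {
  fix <- tiny_cnn()
  x <- fix$X[1, ]
  fmg <- extract_feature_map_gradients(fix$model, x, 2)
  # reconstruct the class score from the flattened maps through the dense
  # head in R, then differentiate numerically
  act <- specfuse:::cpp_cnn_activations(specfuse:::.cnn_net_list(fix$model),
                                        x)
  score_of <- function(flat) {
    h <- flat
    for (d in seq_along(fix$model$dense)) {
      h <- pmax(fix$model$dense[[d]]$W %*% h + fix$model$dense[[d]]$b, 0)
    }
    (fix$model$out$W %*% h + fix$model$out$b)[2]
  }
  expect_equal(score_of(act$flat), fmg$class_score, tolerance = 1e-5)
  eps <- 1e-4
  for (idx in c(1, 7, 20)) {
    up <- act$flat; up[idx] <- up[idx] + eps
    dn <- act$flat; dn[idx] <- dn[idx] - eps
    fd <- (score_of(up) - score_of(dn)) / (2 * eps)
    expect_equal(as.numeric(fmg$gradients)[idx], fd, tolerance = 1e-3)
  }
})

test_that("gradient extraction validates inputs and is deterministic", {
  fix <- tiny_cnn()
  expect_error(extract_feature_map_gradients(fix$model, fix$X[1, ], 9),
               "class_index")
  expect_error(extract_feature_map_gradients(list(), fix$X[1, ], 1),
               "CNN")
  f1 <- extract_feature_map_gradients(fix$model, fix$X[1, ], 1)
  f2 <- extract_feature_map_gradients(fix$model, fix$X[1, ], 1)
  expect_identical(f1$activations, f2$activations)
  expect_identical(f1$gradients, f2$gradients)
  expect_equal(dim(f1$gradients), dim(f1$activations))
})

test_that("CAM upsampling lands on the requested axis length", {
  fix <- tiny_cnn()
  cam <- grad_cam(fix$model, fix$X[1, ], 1)
  expect_length(cam$upsampled, 60)   # input 64 minus the 4 descriptors
  cam2 <- grad_cam(fix$model, fix$X[1, ], 1, target_length = 40)
  expect_length(cam2$upsampled, 40)
  expect_true(all(cam$upsampled >= 0))
})

test_that("CAM summaries aggregate mean and std per class", {
  mk <- function(v) structure(list(raw = v, upsampled = v, class_index = 1L),
                              class = "class_activation_map")
  cams <- list(mk(c(1, 2, 3)), mk(c(1, 2, 3)), mk(c(0, 0, 0)))
  s <- summarize_cam(cams, c("a", "a", "b"), wavelengths = c(10, 20, 30))
  expect_equal(s$classes$a$mean, c(1, 2, 3))
  expect_equal(s$classes$a$sd, c(0, 0, 0))
  expect_equal(s$classes$b$mean, c(0, 0, 0))
  df <- as.data.frame(s)
  expect_equal(nrow(df), 6)
  expect_named(df, c("wavelength_nm", "class", "mean_weight", "std_weight"))
  expect_error(summarize_cam(list(), character(0)), "no activation maps")
})
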