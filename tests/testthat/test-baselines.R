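test_that("KNN with k = 1 memorises distinct training points", {
  tf <- tiny_featurized()
  fit <- fit_baseline("KNN", list(n_neighbors = 1), tf$features, tf$labels)
  expect_equal(mean(predict(fit, tf$features) == tf$labels), 1)
})

test_that("weighted Minkowski KNN agrees with class::knn at p=2 uniform", {
  set.seed(4)
  Xtr <- matrix(rnorm(40 * 6), 40, 6)
  ytr <- factor(rep(c("a", "b"), 20))
  Xte <- matrix(rnorm(15 * 6), 15, 6)
  fit <- fit_baseline("KNN", list(n_neighbors = 3, weights = "uniform",
                                  p = 2), Xtr, ytr)
  mine <- predict(fit, Xte)
  ref <- class::knn(Xtr, Xte, ytr, k = 3)
  # ties can be broken differently; compare where the vote is unambiguous
  prob <- predict(fit, Xte, type = "prob")
  clear <- abs(prob[, 1] - prob[, 2]) > 1e-9
  expect_true(all(as.character(mine[clear]) == as.character(ref[clear])))
})

test_that("PLS-DA predicts labels from the alphabet via arg-max", {
  tf <- tiny_featurized()
  fit <- fit_baseline("PLS-DA", list(n_components = 3), tf$features,
                      tf$labels)
  pred <- predict(fit, tf$features)
  expect_true(all(as.character(pred) %in% sort(unique(tf$labels))))
  expect_gt(mean(pred == tf$labels), 0.25)
})

test_that("hyperparameters outside the tuning ranges are rejected by name", {
  tf <- tiny_featurized()
  expect_error(fit_baseline("RF", list(max_depth = 40), tf$features,
                            tf$labels), "5-30")
  expect_error(fit_baseline("KNN", list(p = 9), tf$features, tf$labels),
               "1-5")
  expect_error(fit_baseline("XGBoost", list(learning_rate = 0.5),
                            tf$features, tf$labels), "0.01-0.3")
  expect_error(fit_baseline("KNN", list(weights = "kernel"), tf$features,
                            tf$labels), "uniform")
})

test_that("every tuned baseline family beats chance on the separable preset", {
  # large enough that the tree learners' min-child constraints can be met
  spec <- dataset_spec(acquisition = tiny_acq(noise_sigma = 20,
                                              pellet_gain_sigma = 0.02,
                                              pellet_offset_sigma = 20),
                       pellets_per_origin = 2, spectra_per_pellet = 12,
                       seed = 21)
  ds <- generate_dataset(spec)
  labels <- dataset_labels(ds)
  scaler <- fit_global_scaler(ds)
  feats <- featurize_records(ds, scaler)
  set.seed(8)
  tr <- sample(length(ds), 72)
  te <- setdiff(seq_along(ds), tr)
  for (fam in c("RF", "KNN", "PLS-DA", "XGBoost")) {
    tuned <- tune_hyperparameters(fam, features = feats[tr, ],
                                  labels = labels[tr], n_trials = 5,
                                  folds = 3, seed = 3)
    fit <- fit_baseline(fam, tuned$best_params, feats[tr, ],
                        labels[tr], seed = 1)
    acc <- mean(predict(fit, feats[te, ]) == labels[te])
    expect_gt(acc, 0.25)
  }
})

test_that("probability outputs have one column per class", {
  tf <- tiny_featurized()
  for (fam in c("RF", "KNN", "XGBoost")) {
    fit <- fit_baseline(fam, list(), tf$features, tf$labels, seed = 1)
    p <- predict(fit, tf$features[1:3, ], type = "prob")
    expect_equal(dim(p), c(3, 4))
    expect_equal(colnames(p), sort(unique(tf$labels)))
  }
})
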