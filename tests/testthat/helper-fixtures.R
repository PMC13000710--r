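# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A fast acquisition: coarse 400-channel grid over the full range with a
# wider line so peaks survive the coarse sampling.
tiny_acq <- function(...) {
  acquisition_spec(n_channels = 400, line_sigma = 1.0, ...)
}

# Small separable dataset (4 origins x 2 pellets x 6 spectra, 400 channels).
tiny_separable <- function() fixture("tiny_separable", function() {
  spec <- dataset_spec(acquisition = tiny_acq(noise_sigma = 20,
                                              pellet_gain_sigma = 0.02,
                                              pellet_offset_sigma = 20),
                       pellets_per_origin = 2, spectra_per_pellet = 6,
                       seed = 42)
  generate_dataset(spec)
})

tiny_featurized <- function() fixture("tiny_featurized", function() {
  ds <- tiny_separable()
  scaler <- fit_global_scaler(ds)
  list(records = ds, scaler = scaler,
       features = featurize_records(ds, scaler),
       labels = dataset_labels(ds))
})

# A trained miniature CNN on a two-class synthetic problem: 64 inputs,
# shallow channels; used by the CNN/Grad-CAM unit tests.
tiny_cnn <- function() fixture("tiny_cnn", function() {
  set.seed(7)
  n <- 48
  X <- matrix(rnorm(n * 64), n, 64)
  y <- rep(c("lo", "hi"), each = n / 2)
  X[y == "hi", 10:14] <- X[y == "hi", 10:14] + 2.5
  cfg <- cnn_config(input_length = 64, n_classes = 2,
                    conv_channels = c(8, 16, 32), dense_sizes = c(32, 16),
                    dropout_rates = c(0.3, 0.2))
  model <- build_cnn(cfg, init_seed = 11)
  model <- train_cnn(model, X, y,
                     train_config(epochs = 25, learning_rate = 1e-3,
                                  batch_size = 8, seed = 3))
  list(model = model, X = X, y = y)
})

expect_setequal_int <- function(a, b) expect_setequal(as.integer(a),
                                                     as.integer(b))
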