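#' Configuration of the feature-fused 1D CNN
#'
#' Default architecture: three convolutional blocks with channel depths
#' 64/128/256, each block a same 1D convolution (kernel 3, padding 1)
#' followed by ReLU, batch normalization and max pooling (size 2); the
#' pooled maps are flattened into dense layers of 256 and 128 units with
#' dropout 0.3/0.2, ending in an `n_classes` softmax. The default input
#' length 6149 is the 6145-channel fused signature plus the four
#' statistical descriptors.
#'
#' @param conv_channels integer vector of channel depths per block.
#' @param kernel_size odd convolution kernel size.
#' @param padding zero padding; must equal `(kernel_size - 1) / 2` (same
#'   convolution).
#' @param pool_size max-pooling window/stride.
#' @param dense_sizes hidden dense layer widths.
#' @param dropout_rates dropout after each hidden dense layer (same
#'   length as `dense_sizes`).
#' @param n_classes number of output classes.
#' @param input_length feature vector length.
#' @return list of class `"cnn_config"`.
#' @export
cnn_config <- function(conv_channels = c(64, 128, 256), kernel_size = 3,
                       padding = 1, pool_size = 2,
                       dense_sizes = c(256, 128),
                       dropout_rates = c(0.3, 0.2), n_classes = 4,
                       input_length = 6149) {
  stopifnot(length(conv_channels) >= 1, all(conv_channels >= 1),
            is_count(kernel_size), is_count(pool_size),
            is_count(n_classes), is_count(input_length, min = 2L))
  if (2 * padding != kernel_size - 1)
    stopf("padding must equal (kernel_size - 1)/2; got kernel %d, padding %s",
          kernel_size, format(padding))
  if (length(dropout_rates) != length(dense_sizes))
    stopf("dropout_rates must match dense_sizes in length")
  if (any(dropout_rates < 0 | dropout_rates >= 1))
    stopf("dropout rates must lie in [0, 1)")
  L <- as.integer(input_length)
  lengths <- integer(0)
  for (i in seq_along(conv_channels)) {
    L <- L %/% pool_size
    lengths <- c(lengths, L)
    if (L < 1)
      stopf("input_length %d too short for %d poolings of size %d",
            input_length, length(conv_channels), pool_size)
  }
  structure(list(conv_channels = as.integer(conv_channels),
                 kernel_size = as.integer(kernel_size),
                 padding = as.integer(padding),
                 pool_size = as.integer(pool_size),
                 dense_sizes = as.integer(dense_sizes),
                 dropout_rates = as.numeric(dropout_rates),
                 n_classes = as.integer(n_classes),
                 input_length = as.integer(input_length),
                 block_lengths = lengths,
                 flatten_size = lengths[length(lengths)] *
                   conv_channels[length(conv_channels)]),
            class = "cnn_config")
}

#' Training protocol for the CNN
#'
#' Defaults follow the reference protocol: 50 epochs of Adam at learning
#' rate 1e-4 with a single-cycle cosine-annealing schedule, batch size 32,
#' cross-entropy loss.
#'
#' @param epochs number of passes over the training set.
#' @param learning_rate initial Adam learning rate.
#' @param batch_size minibatch size.
#' @param seed seed controlling shuffling and dropout; fixed seed gives
#'   bit-reproducible weights.
#' @return list of class `"train_config"`.
#' @export
train_config <- function(epochs = 50, learning_rate = 1e-4,
                         batch_size = 32, seed = 1) {
  stopifnot(is_count(epochs), is_count(batch_size),
            is_scalar_num(learning_rate), learning_rate > 0)
  structure(list(epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build an untrained CNN
#'
#' Initializes convolution and dense weights with He (Kaiming) scaling,
#' batch-norm scale/shift at 1/0, and zero biases. Initialization is
#' deterministic given `init_seed`.
#'
#' @param config a [cnn_config()].
#' @param init_seed seed for weight initialization.
#' @return list of class `"specfuse_cnn"` exposing the conv/dense weights,
#'   final-conv feature-map access (via [extract_feature_map_gradients()])
#'   and a [predict.specfuse_cnn()] method once trained.
#' @export
build_cnn <- function(config = cnn_config(), init_seed = 1) {
  stopifnot(inherits(config, "cnn_config"))
  with_seed(init_seed, {
    he <- function(rows, cols) {
      matrix(rnorm(rows * cols, 0, sqrt(2 / cols)), rows, cols)
    }
    k <- config$kernel_size
    cin <- 1L
    conv <- lapply(config$conv_channels, function(ch) {
      w <- list(W = he(ch, cin * k), b = numeric(ch), gamma = rep(1, ch),
                beta = numeric(ch), running_mean = numeric(ch),
                running_var = rep(1, ch))
      cin <<- ch
      w
    })
    prev <- config$flatten_size
    dense <- lapply(config$dense_sizes, function(d) {
      w <- list(W = he(d, prev), b = numeric(d))
      prev <<- d
      w
    })
    out <- list(W = he(config$n_classes, prev), b = numeric(config$n_classes))
    structure(list(config = config, conv = conv, dense = dense, out = out,
                   trained = FALSE, classes = NULL, loss_history = NULL),
              class = "specfuse_cnn")
  })
}

.cnn_net_list <- function(model) {
  list(config = list(
         input_length = model$config$input_length,
         n_classes = model$config$n_classes,
         kernel_size = model$config$kernel_size,
         padding = model$config$padding,
         pool_size = model$config$pool_size,
         dropout_rates = model$config$dropout_rates),
       conv = model$conv, dense = model$dense, out = model$out)
}

#' Train the CNN
#'
#' Minimizes softmax cross-entropy with Adam under a one-cycle cosine
#' annealing learning-rate schedule. Batch-norm statistics are updated with
#' momentum 0.1; inference after training is deterministic (dropout off,
#' running statistics).
#'
#' @param model a `"specfuse_cnn"` from [build_cnn()].
#' @param features numeric matrix, samples in rows, `input_length` columns.
#' @param labels vector or factor of class labels; its levels define the
#'   label alphabet.
#' @param cfg a [train_config()].
#' @return the trained model, with `loss_history` (mean cross-entropy per
#'   epoch) and the label alphabet in `classes`.
#' @export
train_cnn <- function(model, features, labels, cfg = train_config()) {
  stopifnot(inherits(model, "specfuse_cnn"), inherits(cfg, "train_config"))
  features <- as.matrix(features)
  if (ncol(features) != model$config$input_length)
    stopf("features have %d columns; the model expects %d",
          ncol(features), model$config$input_length)
  y <- if (is.factor(labels)) labels else factor(labels)
  if (nlevels(y) > model$config$n_classes)
    stopf("%d distinct labels exceed the configured n_classes = %d",
          nlevels(y), model$config$n_classes)
  if (any(is.na(y))) stopf("label outside the alphabet (NA after coercion)")
  res <- cpp_cnn_train(.cnn_net_list(model), t(features),
                       as.integer(y) - 1L, cfg$epochs, cfg$learning_rate,
                       cfg$batch_size, cfg$seed, 0.1)
  model$conv <- res$net$conv
  model$dense <- res$net$dense
  model$out <- res$net$out
  model$loss_history <- res$loss
  model$classes <- levels(y)
  model$trained <- TRUE
  model
}

#' Predict with a trained CNN
#'
#' Inference is dropout-free and uses batch-norm running statistics, so
#' repeated calls on the same input are identical.
#'
#' @param object trained `"specfuse_cnn"`.
#' @param features numeric matrix, samples in rows.
#' @param type `"class"` (factor of labels), `"prob"` (softmax matrix) or
#'   `"logit"` (pre-softmax scores).
#' @param ... unused.
#' @return see `type`.
#' @export
predict.specfuse_cnn <- function(object, features,
                                 type = c("class", "prob", "logit"), ...) {
  type <- match.arg(type)
  if (!isTRUE(object$trained)) stopf("model has not been trained")
  features <- as.matrix(features)
  logits <- t(cpp_cnn_forward(.cnn_net_list(object), t(features), 64L))
  colnames(logits) <- object$classes
  if (type == "logit") return(logits)
  if (type == "prob") {
    p <- exp(logits - apply(logits, 1, max))
    return(p / rowSums(p))
  }
  factor(object$classes[max.col(logits, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.specfuse_cnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Feature-fused 1D CNN: input %d -> conv blocks [%s] -> dense [%s] -> %d classes (%s)\n",
    cfg$input_length, paste(cfg$conv_channels, collapse = ", "),
    paste(cfg$dense_sizes, collapse = ", "), cfg$n_classes,
    if (isTRUE(x$trained)) "trained" else "untrained"))
  invisible(x)
}
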