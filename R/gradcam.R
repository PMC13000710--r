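#' Final-conv feature maps and their class-score gradients
#'
#' Runs a single feature vector through the trained CNN in inference mode,
#' captures the final pooled convolutional feature maps `A` (one row per
#' map), and computes the gradient of the pre-softmax class score `Y_c`
#' with respect to those maps by backpropagating through the dense head
#' (whose ReLU/dropout structure is piecewise linear, so the gradient is
#' exact).
#'
#' @param model trained `"specfuse_cnn"`.
#' @param feature_vector numeric vector of length `input_length`.
#' @param class_index class position in the model's label alphabet
#'   (1-based), or a class label.
#' @return list of class `"feature_map_gradients"` with `activations` and
#'   `gradients` (both `K x L` matrices), `class_index`, `class_score`,
#'   and the model input length.
#' @export
extract_feature_map_gradients <- function(model, feature_vector,
                                          class_index) {
  if (!inherits(model, "specfuse_cnn"))
    stopf("Grad-CAM++ requires a CNN model")
  if (!isTRUE(model$trained)) stopf("model has not been trained")
  if (is.character(class_index)) {
    class_index <- match(class_index, model$classes)
    if (is.na(class_index)) stopf("unknown class label")
  }
  if (!is_count(class_index) || class_index > model$config$n_classes)
    stopf("class_index must lie in 1..%d", model$config$n_classes)
  act <- cpp_cnn_activations(.cnn_net_list(model), as.numeric(feature_vector))
  K <- nrow(act$maps)
  L <- ncol(act$maps)
  # gradient of Y_c w.r.t. the dense-head input (the flattened maps)
  g <- as.numeric(model$out$W[class_index, ])
  for (d in rev(seq_along(model$dense))) {
    z <- act$dense_pre[[d]]
    g <- as.numeric(crossprod(model$dense[[d]]$W, g * (z > 0)))
  }
  structure(list(activations = act$maps,
                 gradients = matrix(g, K, L),
                 class_index = class_index,
                 class_score = act$logits[class_index],
                 input_length = model$config$input_length),
            class = "feature_map_gradients")
}

#' Grad-CAM++ location weighting coefficients
#'
#' Computes the closed-form alpha weights. For a piecewise-linear network
#' the higher derivatives of the raw score vanish, so the coefficients are
#' evaluated under the exponential-score reformulation, where the second
#' and third derivatives become `g^2` and `g^3` for first gradient `g`:
#' `alpha = g^2 / (2 g^2 + sum_a A_a g_a^3)` per map. Locations whose
#' denominator is smaller than 1e-12 in magnitude get `alpha = 0`.
#'
#' @param fmg a `"feature_map_gradients"`.
#' @return matrix of alpha weights, same shape as the gradients.
#' @export
compute_alpha_weights <- function(fmg) {
  stopifnot(inherits(fmg, "feature_map_gradients"))
  g <- fmg$gradients
  A <- fmg$activations
  third_sum <- rowSums(A * g^3)        # sum_a A_ak * d3Y/dA^3 per map k
  denom <- 2 * g^2 + third_sum        # recycled per row
  alpha <- g^2 / denom
  alpha[abs(denom) < 1e-12] <- 0
  alpha
}

#' Class activation map
#'
#' Per-map weights `w_k = sum_i alpha_ik * ReLU(g_ik)` combine the feature
#' maps into `ReLU(sum_k w_k A_k)`; the raw map (one value per final-conv
#' location) is then linearly upsampled onto the model input axis, with
#' location `l` mapped to input position `l * (input_length - 1) / (L - 1)`,
#' and truncated to the first `target_length` (spectral) positions so the
#' four trailing statistical descriptors are excluded from the wavelength
#' axis.
#'
#' @param fmg a `"feature_map_gradients"`.
#' @param alpha alpha weights from [compute_alpha_weights()].
#' @param target_length length of the reported curve; defaults to
#'   `input_length - 4`.
#' @return list of class `"class_activation_map"` with `raw`, `upsampled`
#'   and `class_index`. All values are non-negative.
#' @export
compute_cam <- function(fmg, alpha, target_length = NULL) {
  stopifnot(inherits(fmg, "feature_map_gradients"))
  target_length <- target_length %||% (fmg$input_length - 4L)
  w <- rowSums(alpha * pmax(fmg$gradients, 0))
  raw <- pmax(as.numeric(crossprod(fmg$activations, w)), 0)
  L <- length(raw)
  pos <- if (L > 1) seq(0, fmg$input_length - 1, length.out = L) else 0
  up <- if (L > 1) {
    approx(pos, raw, xout = seq(0, fmg$input_length - 1))$y
  } else rep(raw, fmg$input_length)
  structure(list(raw = raw,
                 upsampled = up[seq_len(target_length)],
                 class_index = fmg$class_index),
            class = "class_activation_map")
}

#' One-call Grad-CAM++ for a single sample
#'
#' @inheritParams extract_feature_map_gradients
#' @inheritParams compute_cam
#' @return a `"class_activation_map"`.
#' @export
grad_cam <- function(model, feature_vector, class_index,
                     target_length = NULL) {
  fmg <- extract_feature_map_gradients(model, feature_vector, class_index)
  compute_cam(fmg, compute_alpha_weights(fmg), target_length)
}

#' Cross-sample activation-map stability summary
#'
#' For each class, computes the per-wavelength mean and standard deviation
#' of the upsampled activation maps across samples. A low standard
#' deviation marks a spectral region the network activates consistently
#' for that class; a high one marks intra-class variability.
#'
#' @param cams list of `"class_activation_map"` objects.
#' @param classes class label of each map (parallel to `cams`).
#' @param wavelengths optional wavelength axis matching the upsampled
#'   length.
#' @return list of class `"cam_summary"`: per class a list with `mean` and
#'   `sd` curves; convert with [as.data.frame.cam_summary()].
#' @export
summarize_cam <- function(cams, classes, wavelengths = NULL) {
  if (length(cams) == 0) stopf("no activation maps supplied")
  if (length(cams) != length(classes))
    stopf("cams and classes differ in length")
  groups <- split(cams, factor(classes))
  if (any(vapply(groups, length, integer(1)) == 0))
    stopf("empty class group")
  out <- lapply(groups, function(g) {
    M <- do.call(rbind, lapply(g, function(cam) cam$upsampled))
    list(mean = colMeans(M),
         sd = if (nrow(M) > 1) apply(M, 2, sd) else numeric(ncol(M)))
  })
  structure(list(classes = out, wavelengths = wavelengths),
            class = "cam_summary")
}

#' @describeIn summarize_cam flatten a summary to a long data frame with
#'   columns `wavelength_nm` (or position index), `class`, `mean_weight`,
#'   `std_weight`.
#' @param x a `"cam_summary"`.
#' @param ... unused.
#' @export
as.data.frame.cam_summary <- function(x, ...) {
  do.call(rbind, lapply(names(x$classes), function(cl) {
    cu <- x$classes[[cl]]
    data.frame(
      wavelength_nm = x$wavelengths %||% seq_along(cu$mean),
      class = cl, mean_weight = cu$mean, std_weight = cu$sd,
      row.names = NULL)
  }))
}
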