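#' Fit the global min-max scaler on training records
#'
#' The scaler boundaries are the joint extrema of the training wavelengths
#' and intensities pooled together: `v_min = min(min lambda, min I)` and
#' `v_max = max(max lambda, max I)`. Pooling both quantities into one pair
#' of boundaries maps spectral position and radiometric response into a
#' common latent range so the fused signature (normalized wavelength +
#' normalized intensity) is well scaled. Only the records passed in are
#' consulted -- pass training records exclusively to keep the transform
#' leakage-safe for held-out data.
#'
#' An alternative `mode = "per_vector"` scales wavelengths and intensities
#' by their own extrema; it is off by default.
#'
#' @param records list of spectrum records (training partition only).
#' @param epsilon regularizer added to the denominator to prevent
#'   singularity when `v_max == v_min`.
#' @param mode `"joint"` (default) or `"per_vector"`.
#' @return a list of class `"scaler_params"`.
#' @export
fit_global_scaler <- function(records, epsilon = 1e-12,
                              mode = c("joint", "per_vector")) {
  mode <- match.arg(mode)
  if (length(records) == 0) stopf("cannot fit a scaler on an empty training set")
  if (!is_scalar_num(epsilon) || epsilon <= 0)
    stopf("epsilon must be a positive scalar")
  wl_rng <- range(vapply(records, function(r) range(r$wavelengths),
                         numeric(2)))
  in_rng <- range(vapply(records, function(r) range(r$intensities),
                         numeric(2)))
  if (mode == "joint") {
    params <- list(v_min = min(wl_rng[1], in_rng[1]),
                   v_max = max(wl_rng[2], in_rng[2]),
                   epsilon = epsilon, mode = mode)
  } else {
    params <- list(v_min = c(lambda = wl_rng[1], intensity = in_rng[1]),
                   v_max = c(lambda = wl_rng[2], intensity = in_rng[2]),
                   epsilon = epsilon, mode = mode)
  }
  structure(params, class = "scaler_params")
}

#' Apply a fitted min-max scaler
#'
#' Computes `(x - v_min) / (v_max - v_min + epsilon)` elementwise. Values
#' outside the training range map outside `[0, 1]` and are deliberately not
#' clipped: held-out data must not be re-scaled by its own extrema.
#'
#' @param values numeric vector.
#' @param params a `"scaler_params"` from [fit_global_scaler()].
#' @param which for `mode = "per_vector"` scalers, `"lambda"` or
#'   `"intensity"`; ignored for joint scalers.
#' @return scaled numeric vector.
#' @export
apply_scaler <- function(values, params, which = c("intensity", "lambda")) {
  stopifnot(inherits(params, "scaler_params"))
  if (params$mode == "joint") {
    (values - params$v_min) / (params$v_max - params$v_min + params$epsilon)
  } else {
    which <- match.arg(which)
    (values - params$v_min[[which]]) /
      (params$v_max[[which]] - params$v_min[[which]] + params$epsilon)
  }
}

#' Fused spectral signature
#'
#' Element-wise sum of the normalized wavelength and intensity vectors.
#'
#' @param lambda_norm,intensity_norm equal-length numeric vectors.
#' @return numeric vector of the same length.
#' @export
fuse_signature <- function(lambda_norm, intensity_norm) {
  if (length(lambda_norm) != length(intensity_norm))
    stopf("lambda_norm (%d) and intensity_norm (%d) differ in length",
          length(lambda_norm), length(intensity_norm))
  lambda_norm + intensity_norm
}

#' Detect diagnostic peaks
#'
#' A peak is a strict two-neighbour local maximum whose value exceeds the
#' dynamic amplitude threshold `0.8 * max(x)`. Endpoints are excluded and
#' plateaus yield no peak (strict inequalities), which makes the threshold
#' rule deterministic.
#'
#' @param intensity_norm numeric vector (normalized intensities).
#' @return integer vector of peak indices (1-based, ordered); empty if the
#'   input has fewer than 3 points.
#' @export
detect_peaks <- function(intensity_norm) {
  n <- length(intensity_norm)
  if (n < 3) return(integer(0))
  x <- intensity_norm
  i <- 2:(n - 1)
  local_max <- x[i] > x[i - 1] & x[i] > x[i + 1]
  above <- x[i] > 0.8 * max(x)
  i[local_max & above]
}

#' Statistical descriptors of a normalized spectrum
#'
#' Computes the peak count `Np`, mean peak intensity (0 when no peaks),
#' global mean intensity, and the population standard deviation (divisor
#' `N`, not `N - 1`).
#'
#' @param intensity_norm numeric vector.
#' @param peaks integer indices from [detect_peaks()] on the same vector.
#' @return list with `n_peaks`, `mean_peak_intensity`, `mean_intensity`,
#'   `std_intensity`.
#' @export
compute_descriptors <- function(intensity_norm, peaks) {
  n <- length(intensity_norm)
  np <- length(peaks)
  mu_p <- if (np > 0) mean(intensity_norm[peaks]) else 0
  mu_g <- mean(intensity_norm)
  sd_g <- sqrt(sum((intensity_norm - mu_g)^2) / n)
  list(n_peaks = np, mean_peak_intensity = mu_p,
       mean_intensity = mu_g, std_intensity = sd_g)
}

#' Assemble the final feature vector
#'
#' Concatenates the fused signature with the four statistical descriptors
#' in the fixed order: peak count, mean peak intensity, mean signal
#' intensity, standard deviation. The descriptors are appended unscaled.
#'
#' @param fused numeric vector of length N.
#' @param stats descriptor list from [compute_descriptors()].
#' @return numeric vector of length N + 4.
#' @export
assemble_feature_vector <- function(fused, stats) {
  c(fused, stats$n_peaks, stats$mean_peak_intensity,
    stats$mean_intensity, stats$std_intensity)
}

#' Full preprocessing of one record
#'
#' Normalizes wavelengths and intensities with a frozen scaler, fuses them,
#' detects peaks, and appends the statistical descriptors.
#'
#' @param record a spectrum record.
#' @param params fitted `"scaler_params"`.
#' @return numeric feature vector of length `n_channels + 4`.
#' @export
feature_vector <- function(record, params) {
  ln <- apply_scaler(record$wavelengths, params, which = "lambda")
  int <- apply_scaler(record$intensities, params, which = "intensity")
  fused <- fuse_signature(ln, int)
  stats <- compute_descriptors(int, detect_peaks(int))
  assemble_feature_vector(fused, stats)
}

#' Featurize a list of records into a model input matrix
#'
#' @param records list of spectrum records.
#' @param params fitted `"scaler_params"`.
#' @return numeric matrix, one row per record, `n_channels + 4` columns.
#' @export
featurize_records <- function(records, params) {
  t(vapply(records, feature_vector,
           numeric(length(records[[1]]$wavelengths) + 4), params = params))
}

#' Serialize / restore scaler parameters as JSON
#'
#' @param params a `"scaler_params"`.
#' @param path file path.
#' @return `read_scaler` returns a `"scaler_params"`.
#' @export
write_scaler <- function(params, path) {
  stopifnot(inherits(params, "scaler_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scaler
#' @export
read_scaler <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(v_min = obj$v_min, v_max = obj$v_max,
                 epsilon = obj$epsilon, mode = obj$mode %||% "joint"),
            class = "scaler_params")
}
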