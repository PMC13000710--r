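#' Noise sweep specification
#'
#' Signal-to-noise levels for the robustness stress test, ordered from the
#' clean signal (`Inf`) down to 20 dB.
#'
#' @param snr_levels_db numeric vector of SNR levels in dB; `Inf` means no
#'   added noise.
#' @param seed integer seed for the noise draws.
#' @return list of class `"noise_spec"`.
#' @export
noise_spec <- function(snr_levels_db = c(Inf, 50, 40, 30, 20), seed = 1) {
  if (length(snr_levels_db) == 0 || any(is.na(snr_levels_db)))
    stopf("snr_levels_db must be a non-empty numeric vector")
  structure(list(snr_levels_db = as.numeric(snr_levels_db),
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Add white Gaussian noise at a target SNR
#'
#' Noise variance is set against the mean-square raw intensity of the
#' spectrum: `sigma^2 = mean(I^2) / 10^(snr_db / 10)`, the standard AWGN
#' convention. Applied to raw intensities, i.e. before any (frozen)
#' preprocessing. Corrupted intensities are deliberately not clipped at
#' zero, so the injected noise power is exactly the nominal one; a
#' corrupted record is a test-time perturbation, not a simulator output.
#' Noise comes from the caller's RNG stream. `snr_db = Inf` returns the
#' record unchanged.
#'
#' @param record a spectrum record.
#' @param snr_db target signal-to-noise ratio in dB.
#' @return a corrupted `"spectrum_record"`.
#' @export
add_awgn <- function(record, snr_db) {
  if (is.na(snr_db)) stopf("snr_db must not be NA")
  if (is.infinite(snr_db)) return(record)
  power <- mean(record$intensities^2)
  if (power == 0) stopf("SNR undefined for an all-zero spectrum")
  sigma <- sqrt(power / 10^(snr_db / 10))
  record$intensities <- record$intensities +
    rnorm(length(record$intensities), 0, sigma)
  record
}

#' SNR-swept robustness stress test
#'
#' For each SNR level the raw held-out spectra are corrupted with white
#' Gaussian noise, passed through the frozen training-fit preprocessing,
#' and evaluated by every clean-trained fold model; the curve reports the
#' mean and standard deviation of accuracy across the fold ensemble. No
#' model is retrained under noise.
#'
#' @param fold_models list of trained models (CNN or baselines).
#' @param test_records held-out spectrum records.
#' @param scaler frozen `"scaler_params"` fitted on training data.
#' @param noise a [noise_spec()].
#' @return data frame with columns `snr_db`, `mean_acc`, `sd_acc`; the
#'   per-model accuracy matrix is attached as attribute `"per_model"`.
#' @export
stress_test <- function(fold_models, test_records, scaler,
                        noise = noise_spec()) {
  if (length(fold_models) == 0) stopf("empty model list")
  stopifnot(inherits(noise, "noise_spec"))
  labels <- dataset_labels(test_records)
  acc <- matrix(NA_real_, length(noise$snr_levels_db), length(fold_models))
  for (li in seq_along(noise$snr_levels_db)) {
    level <- noise$snr_levels_db[li]
    corrupted <- with_seed(child_seed(noise$seed, paste0("snr", li)),
                           lapply(test_records, add_awgn, snr_db = level))
    feats <- featurize_records(corrupted, scaler)
    for (mi in seq_along(fold_models)) {
      pred <- predict(fold_models[[mi]], feats)
      acc[li, mi] <- mean(as.character(pred) == labels)
    }
  }
  out <- data.frame(snr_db = noise$snr_levels_db,
                    mean_acc = rowMeans(acc),
                    sd_acc = apply(acc, 1, sd))
  attr(out, "per_model") <- acc
  out
}
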