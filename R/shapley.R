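#' Select the top-k diagnostic spectral channels
#'
#' Ranks channels that are detected as peaks in at least one training
#' spectrum by their mean normalized intensity across the training set,
#' breaking ties by ascending wavelength, and returns the top `k`. These
#' reduced representations feed the Shapley attribution of the shallow
#' models.
#'
#' @param records training spectrum records.
#' @param scaler frozen `"scaler_params"`.
#' @param k number of channels (default 10).
#' @return integer channel indices, best first. If fewer than `k` peak
#'   channels exist, all are returned with a warning.
#' @export
select_top_features <- function(records, scaler, k = 10) {
  stopifnot(is_count(k))
  norm <- lapply(records, function(r) apply_scaler(r$intensities, scaler,
                                                   which = "intensity"))
  peak_channels <- sort(unique(unlist(lapply(norm, detect_peaks))))
  if (length(peak_channels) == 0) {
    warnf("no peaks detected in the training records")
    return(integer(0))
  }
  mean_int <- Reduce(`+`, norm) / length(norm)
  ord <- peak_channels[order(-mean_int[peak_channels], peak_channels)]
  if (length(ord) < k) {
    warnf("only %d peak channels available (requested %d)", length(ord), k)
    return(ord)
  }
  ord[seq_len(k)]
}

# Shapley kernel weight for a coalition of size s out of m features.
.shapley_kernel <- function(m, s) {
  (m - 1) / (choose(m, s) * s * (m - s))
}

#' Shapley-value feature attribution
#'
#' Attributes a model output to individual features of one instance
#' against a background reference. Absent features are replaced by the
#' background values. Two modes:
#' * `"exact"`: enumerates all `2^m` coalitions and averages marginal
#'   contributions with the exact Shapley weights (m <= 15).
#' * `"sampled"`: kernel-weighted least squares on sampled coalitions
#'   (KernelSHAP); when `n_samples` covers the full coalition set the
#'   enumeration is complete and the result matches exact attribution.
#'
#' The efficiency axiom `phi0 + sum(phi) = f(instance)` holds exactly in
#' exact mode and by construction (equality-constrained regression) in
#' sampled mode.
#'
#' @param predict_fn function mapping a numeric matrix (rows = instances)
#'   to a numeric vector or matrix of model outputs (columns = outputs,
#'   e.g. per-class scores).
#' @param instance numeric vector of feature values to explain.
#' @param background numeric vector of reference feature values (e.g. the
#'   feature-wise training mean).
#' @param mode `"exact"` or `"sampled"`.
#' @param n_samples coalition budget for sampled mode.
#' @param seed seed for coalition sampling.
#' @return list of class `"shapley_attribution"`: `phi` (features x
#'   outputs), `phi0` (output for the all-background instance), `fx`
#'   (output for the instance), `features`.
#' @export
shapley_attribution <- function(predict_fn, instance, background,
                                mode = c("exact", "sampled"),
                                n_samples = 2048, seed = 1) {
  mode <- match.arg(mode)
  m <- length(instance)
  if (length(background) != m)
    stopf("instance and background differ in length")
  if (m < 1) stopf("at least one feature is required")
  eval_masks <- function(Z) {
    # Z: logical matrix (n x m); TRUE -> instance value
    X <- matrix(rep(background, each = nrow(Z)), nrow(Z), m)
    X[Z] <- matrix(rep(instance, each = nrow(Z)), nrow(Z), m)[Z]
    out <- predict_fn(X)
    if (is.null(dim(out))) out <- matrix(out, ncol = 1)
    out
  }
  ends <- eval_masks(rbind(rep(FALSE, m), rep(TRUE, m)))
  phi0 <- ends[1, ]
  fx <- ends[2, ]
  n_out <- length(phi0)

  if (mode == "exact") {
    if (m > 15)
      stopf("exact mode enumerates 2^m coalitions; m = %d > 15, use mode = 'sampled'", m)
    masks <- 0:(2^m - 1)
    Z <- t(vapply(masks, function(msk)
      as.logical(bitwAnd(msk, bitwShiftL(1L, 0:(m - 1)))), logical(m)))
    v <- eval_masks(Z)                 # (2^m) x n_out
    sizes <- rowSums(Z)
    fact <- factorial(0:m)
    phi <- matrix(0, m, n_out)
    for (j in seq_len(m)) {
      bit <- bitwShiftL(1L, j - 1L)
      without <- which(bitwAnd(masks, bit) == 0L)
      s <- sizes[without]
      w <- fact[s + 1] * fact[m - s] / fact[m + 1]
      gain <- v[masks[without] + bit + 1L, , drop = FALSE] -
              v[without, , drop = FALSE]
      phi[j, ] <- colSums(gain * w)
    }
  } else {
    full <- 2^m - 2                    # proper, non-trivial coalitions
    if (n_samples >= full && m <= 25) {
      masks <- setdiff(0:(2^m - 1), c(0, 2^m - 1))
      Z <- t(vapply(masks, function(msk)
        as.logical(bitwAnd(msk, bitwShiftL(1L, 0:(m - 1)))), logical(m)))
      wts <- .shapley_kernel(m, rowSums(Z))
    } else {
      sizes_all <- 1:(m - 1)
      size_prob <- (m - 1) / (sizes_all * (m - sizes_all))
      Z <- with_seed(seed, {
        s <- sample(sizes_all, n_samples, replace = TRUE,
                    prob = size_prob / sum(size_prob))
        t(vapply(s, function(si) {
          z <- logical(m)
          z[sample.int(m, si)] <- TRUE
          z
        }, logical(m)))
      })
      wts <- rep(1, nrow(Z))           # size distribution already kernel-shaped
    }
    v <- eval_masks(Z)
    # equality-constrained weighted least squares:
    # v - phi0 = Z phi with sum(phi) = fx - phi0; eliminate phi_m
    total <- fx - phi0
    Zl <- Z[, -m, drop = FALSE] - Z[, m]
    phi <- matrix(0, m, n_out)
    A <- sweep(Zl, 1, sqrt(wts), "*")
    for (o in seq_len(n_out)) {
      yv <- (v[, o] - phi0[o] - Z[, m] * total[o]) * sqrt(wts)
      if (m == 1) {
        phi[1, o] <- total[o]
        next
      }
      coef <- tryCatch(qr.coef(qr(A), yv), error = function(e)
        stopf("kernel regression failed: %s", conditionMessage(e)))
      coef[is.na(coef)] <- 0
      phi[seq_len(m - 1), o] <- coef
      phi[m, o] <- total[o] - sum(coef)
    }
  }
  dimnames(phi) <- list(names(instance) %||% paste0("x", seq_len(m)),
                        colnames(ends))
  structure(list(phi = phi, phi0 = phi0, fx = fx,
                 features = rownames(phi), mode = mode),
            class = "shapley_attribution")
}

#' @export
print.shapley_attribution <- function(x, ...) {
  cat(sprintf("Shapley attribution (%s mode), %d feature(s)\n",
              x$mode, nrow(x$phi)))
  print(round(x$phi, 4))
  resid <- x$phi0 + colSums(x$phi) - x$fx
  cat(sprintf("efficiency residual: %s\n",
              paste(format(resid, digits = 3), collapse = ", ")))
  invisible(x)
}
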