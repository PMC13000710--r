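#' Acquisition settings for the synthetic spectrometer
#'
#' Describes the fixed wavelength grid and the nuisance structure of a
#' simulated LIBS acquisition: Gaussian line width, a smooth quadratic
#' continuum, additive detector noise, and pellet-level gain/offset
#' variation shared by all spectra from one pressed pellet.
#'
#' @param lambda_min,lambda_max wavelength range in nm (default 200-550).
#' @param n_channels number of grid points (default 6145, ~0.057 nm step).
#' @param line_sigma Gaussian line width (standard deviation) in nm.
#'   The 0.15 nm default resolves the closest pair of library lines
#'   (403.33/404.42 nm) on the default grid.
#' @param baseline_coeffs quadratic continuum coefficients `c(b0, b1, b2)`
#'   evaluated as `b0 + b1*u + b2*u^2` on the normalized coordinate
#'   `u = (lambda - lambda_min) / (lambda_max - lambda_min)`; the default
#'   peaks at ~2% of the tallest default emission peak.
#' @param noise_sigma standard deviation of additive Gaussian detector
#'   noise, counts.
#' @param pellet_gain_sigma standard deviation of the multiplicative
#'   per-pellet gain (mean 1) applied to the emission-line component.
#' @param pellet_offset_sigma standard deviation of the additive per-pellet
#'   baseline shift, counts.
#' @param shot_gain_sigma standard deviation of the multiplicative
#'   per-spectrum (shot-to-shot) gain jitter; emulates residual pulse-to-
#'   pulse plasma fluctuation after pulse averaging.
#' @param shot_offset_sigma standard deviation of the additive per-spectrum
#'   baseline drift, counts.
#' @param pellet_tilt_sigma,shot_tilt_sigma standard deviations of a
#'   wavelength-dependent baseline tilt (counts across the full range,
#'   applied as `tilt * (u - 0.5)` on the normalized wavelength
#'   coordinate), drawn per pellet and per spectrum respectively;
#'   emulates continuum-shape drift with plasma conditions.
#' @return a list of class `"acquisition_spec"`.
#' @export
acquisition_spec <- function(lambda_min = 200, lambda_max = 550,
                             n_channels = 6145, line_sigma = 0.15,
                             baseline_coeffs = c(120, 160, -80),
                             noise_sigma = 20, pellet_gain_sigma = 0.02,
                             pellet_offset_sigma = 20,
                             shot_gain_sigma = 0.02,
                             shot_offset_sigma = 0,
                             pellet_tilt_sigma = 0,
                             shot_tilt_sigma = 0) {
  if (!is_scalar_num(lambda_min) || !is_scalar_num(lambda_max) ||
      lambda_min >= lambda_max)
    stopf("lambda_min must be < lambda_max")
  if (!is_count(n_channels, min = 2L))
    stopf("n_channels must be an integer >= 2")
  sig <- c(line_sigma, noise_sigma, pellet_gain_sigma, pellet_offset_sigma,
           shot_gain_sigma, shot_offset_sigma, pellet_tilt_sigma,
           shot_tilt_sigma)
  if (any(!is.finite(sig)) || any(sig < 0))
    stopf("all sigma parameters must be finite and >= 0")
  structure(list(lambda_min = lambda_min, lambda_max = lambda_max,
                 n_channels = as.integer(n_channels),
                 line_sigma = line_sigma,
                 baseline_coeffs = baseline_coeffs,
                 noise_sigma = noise_sigma,
                 pellet_gain_sigma = pellet_gain_sigma,
                 pellet_offset_sigma = pellet_offset_sigma,
                 shot_gain_sigma = shot_gain_sigma,
                 shot_offset_sigma = shot_offset_sigma,
                 pellet_tilt_sigma = pellet_tilt_sigma,
                 shot_tilt_sigma = shot_tilt_sigma),
            class = "acquisition_spec")
}

#' Dataset layout for the synthetic study
#'
#' The default layout reproduces the reference acquisition design:
#' 4 origins x 4 pellets x 50 spectra = 800 records.
#'
#' @param profiles list of origin profiles (see [origin_profile()]).
#' @param pellets_per_origin pellets pressed per origin (default 4).
#' @param spectra_per_pellet spectra acquired per pellet (default 50).
#' @param acquisition an [acquisition_spec()].
#' @param lines optional emission-line library; defaults to
#'   [default_line_library()] normalized over `profiles`.
#' @param seed integer seed; datasets are bit-reproducible given the spec.
#' @return a list of class `"dataset_spec"`.
#' @export
dataset_spec <- function(profiles = default_origin_profiles(),
                         pellets_per_origin = 4, spectra_per_pellet = 50,
                         acquisition = acquisition_spec(), lines = NULL,
                         seed = 42) {
  if (length(profiles) == 0)
    stopf("at least one origin profile is required")
  stopifnot(is_count(pellets_per_origin), is_count(spectra_per_pellet))
  structure(list(profiles = profiles,
                 pellets_per_origin = as.integer(pellets_per_origin),
                 spectra_per_pellet = as.integer(spectra_per_pellet),
                 acquisition = acquisition,
                 lines = lines,
                 seed = as.integer(seed)),
            class = "dataset_spec")
}

#' Preset dataset specifications
#'
#' Two study conditions are shipped:
#' * `"separable"`: mild nuisance variation (2% pellet gain spread, small
#'   baseline shifts) so class structure dominates; used for accuracy and
#'   robustness experiments.
#' * `"confounded"`: strong pellet effects (60% gain spread, baseline
#'   shifts an order of magnitude above the continuum) plus heavy detector
#'   noise, calibrated so the label-independent nuisance dominates the
#'   unsupervised structure of the data (negative label silhouette on
#'   z-scored spectra), emulating the systematic background variance seen
#'   in real pressed-pellet acquisitions.
#'
#' @param preset `"separable"` or `"confounded"`.
#' @param seed integer seed.
#' @param ... further arguments passed to [dataset_spec()].
#' @return a `"dataset_spec"`.
#' @export
preset_dataset_spec <- function(preset = c("separable", "confounded"),
                                seed = 42, ...) {
  preset <- match.arg(preset)
  acq <- switch(preset,
    separable = acquisition_spec(noise_sigma = 20,
                                 pellet_gain_sigma = 0.02,
                                 pellet_offset_sigma = 20),
    confounded = acquisition_spec(noise_sigma = 600,
                                  pellet_gain_sigma = 0.30,
                                  pellet_offset_sigma = 1000,
                                  shot_gain_sigma = 0.10,
                                  shot_offset_sigma = 800,
                                  pellet_tilt_sigma = 1000,
                                  shot_tilt_sigma = 800))
  dataset_spec(acquisition = acq, seed = seed, ...)
}

#' Render a single synthetic LIBS spectrum
#'
#' Evaluates, on the uniform wavelength grid,
#' `I(lambda) = gain * sum_lines A_l exp(-(lambda - lambda_l)^2 / (2 sigma^2))
#'  + baseline(lambda) + offset + noise`, with line amplitude
#' `A_l = emissivity_l * concentration(element_l)`, then clips at zero
#' (detector counts are non-negative). Elements present in the line library
#' but absent from the profile contribute zero. Noise is drawn from the
#' caller's RNG stream; seed it for reproducibility.
#'
#' @param profile an [origin_profile()].
#' @param lines line library data frame (see [default_line_library()]).
#' @param acq an [acquisition_spec()].
#' @param pellet_gain multiplicative gain applied to the line component.
#' @param pellet_offset additive baseline shift, counts.
#' @return a `"spectrum_record"`: list with `origin`, `pellet_id`,
#'   `wavelengths`, `intensities`.
#' @export
render_spectrum <- function(profile, lines, acq, pellet_gain = 1,
                            pellet_offset = 0, pellet_tilt = 0) {
  wl <- seq(acq$lambda_min, acq$lambda_max, length.out = acq$n_channels)
  signal <- numeric(acq$n_channels)
  for (i in seq_len(nrow(lines))) {
    conc <- unname(profile$concentrations[lines$element[i]])
    if (length(conc) == 0 || is.na(conc) || conc == 0) next
    amp <- lines$emissivity[i] * conc
    centre <- lines$wavelength_nm[i]
    # evaluate only within +-6 sigma of the centre
    lo <- findInterval(centre - 6 * acq$line_sigma, wl) + 1L
    hi <- findInterval(centre + 6 * acq$line_sigma, wl)
    if (hi < lo) next
    idx <- lo:hi
    signal[idx] <- signal[idx] +
      amp * exp(-(wl[idx] - centre)^2 / (2 * acq$line_sigma^2))
  }
  u <- (wl - acq$lambda_min) / (acq$lambda_max - acq$lambda_min)
  bc <- acq$baseline_coeffs
  baseline <- bc[1] + bc[2] * u + bc[3] * u^2
  shot_gain <- if (acq$shot_gain_sigma > 0)
    max(rnorm(1, 1, acq$shot_gain_sigma), 0.05) else 1
  shot_offset <- if (acq$shot_offset_sigma > 0)
    rnorm(1, 0, acq$shot_offset_sigma) else 0
  shot_tilt <- if (acq$shot_tilt_sigma > 0)
    rnorm(1, 0, acq$shot_tilt_sigma) else 0
  noise <- if (acq$noise_sigma > 0)
    rnorm(acq$n_channels, 0, acq$noise_sigma) else 0
  intensity <- pellet_gain * shot_gain * signal + baseline +
    pellet_offset + shot_offset + (pellet_tilt + shot_tilt) * (u - 0.5) +
    noise
  spectrum_record(profile$origin, pellet_id = NA_character_,
                  wavelengths = wl, intensities = pmax(intensity, 0))
}

#' Construct a spectrum record
#'
#' @param origin class label.
#' @param pellet_id replicate (pellet) identifier.
#' @param wavelengths strictly increasing numeric vector, nm.
#' @param intensities non-negative numeric vector, same length.
#' @return a list of class `"spectrum_record"`.
#' @export
spectrum_record <- function(origin, pellet_id, wavelengths, intensities) {
  if (length(wavelengths) != length(intensities))
    stopf("wavelengths and intensities must have equal length")
  if (any(diff(wavelengths) <= 0))
    stopf("wavelengths must be strictly increasing")
  if (any(intensities < 0))
    stopf("intensities must be non-negative")
  structure(list(origin = origin, pellet_id = pellet_id,
                 wavelengths = wavelengths, intensities = intensities),
            class = "spectrum_record")
}

#' Generate a labeled synthetic dataset
#'
#' Draws one (gain, offset) pair per pellet -- shared by all spectra of that
#' pellet, which creates the label-independent nuisance structure of real
#' pressed-pellet acquisitions -- and renders
#' `length(profiles) * pellets_per_origin * spectra_per_pellet` records.
#' Deterministic given `spec$seed`; the caller's RNG state is untouched.
#'
#' @param spec a [dataset_spec()].
#' @return list of `"spectrum_record"`, with class `"spectrum_dataset"`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "dataset_spec"))
  if (length(spec$profiles) == 0) stopf("empty profile list")
  lines <- spec$lines %||% default_line_library(spec$profiles)
  acq <- spec$acquisition
  with_seed(spec$seed, {
    records <- vector("list",
      length(spec$profiles) * spec$pellets_per_origin * spec$spectra_per_pellet)
    n <- 0L
    for (profile in spec$profiles) {
      for (p in seq_len(spec$pellets_per_origin)) {
        gain <- max(rnorm(1, 1, acq$pellet_gain_sigma), 0.05)
        offset <- rnorm(1, 0, acq$pellet_offset_sigma)
        tilt <- if (acq$pellet_tilt_sigma > 0)
          rnorm(1, 0, acq$pellet_tilt_sigma) else 0
        pid <- sprintf("%s_p%d", profile$origin, p)
        for (s in seq_len(spec$spectra_per_pellet)) {
          rec <- render_spectrum(profile, lines, acq, gain, offset, tilt)
          rec$pellet_id <- pid
          n <- n + 1L
          records[[n]] <- rec
        }
      }
    }
    structure(records, class = "spectrum_dataset")
  })
}

#' Extract labels, pellet ids or the intensity matrix from a dataset
#'
#' @param records list of spectrum records.
#' @return `dataset_labels`/`dataset_pellets`: character vector;
#'   `intensity_matrix`: numeric matrix, records in rows.
#' @export
dataset_labels <- function(records) {
  vapply(records, function(r) r$origin, character(1))
}

#' @rdname dataset_labels
#' @export
dataset_pellets <- function(records) {
  vapply(records, function(r) r$pellet_id, character(1))
}

#' @rdname dataset_labels
#' @export
intensity_matrix <- function(records) {
  do.call(rbind, lapply(records, function(r) r$intensities))
}
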