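make_rec <- function(wl, int) spectrum_record("x", "p", wl, int)

test_that("global scaler pools wavelength and intensity extrema", {
  r1 <- make_rec(seq(200, 550, length.out = 50),
                 seq(0, 1000, length.out = 50))
  s <- fit_global_scaler(list(r1))
  expect_equal(s$v_min, 0)
  expect_equal(s$v_max, 1000)
  r2 <- make_rec(seq(200, 550, length.out = 50),
                 seq(5, 80, length.out = 50))
  s2 <- fit_global_scaler(list(r2))
  expect_equal(s2$v_min, 5)
  expect_equal(s2$v_max, 550)
  expect_error(fit_global_scaler(list()), "empty")
})

test_that("scaler parameters never consult held-out records", {
  ds <- tiny_separable()
  train <- ds[1:30]
  s_before <- fit_global_scaler(train)
  # mutate a held-out record to an extreme value; the scaler is unchanged
  held <- ds[[31]]
  held$intensities[5] <- 1e6
  s_after <- fit_global_scaler(train)
  expect_identical(s_before, s_after)
  expect_lt(s_after$v_max, 1e6)
})

test_that("apply_scaler is the printed affine map, without clipping", {
  s <- structure(list(v_min = 10, v_max = 110, epsilon = 1e-12,
                      mode = "joint"), class = "scaler_params")
  expect_equal(apply_scaler(10, s), 0)
  expect_equal(apply_scaler(110, s), 1, tolerance = 1e-10)
  # a value one full span above v_max maps to ~2: leakage-safe extrapolation
  expect_equal(apply_scaler(210, s), 2, tolerance = 1e-10)
})

test_that("fuse_signature adds the normalized vectors elementwise", {
  expect_equal(fuse_signature(c(0.1, 0.2), c(0.3, 0.4)), c(0.4, 0.6))
  lam <- runif(6145)
  expect_equal(fuse_signature(lam, numeric(6145)), lam)
  expect_length(fuse_signature(runif(6145), runif(6145)), 6145)
  expect_error(fuse_signature(1:3, 1:2), "length")
})

test_that("detect_peaks finds strict local maxima above 0.8 max", {
  x <- c(0, 1, 0, 0.9, 0, 0.5, 0)
  expect_equal(detect_peaks(x), c(2L, 4L))       # 1-based indices
  expect_equal(detect_peaks(c(0, 0.5, 1)), integer(0))  # endpoint max
  expect_equal(detect_peaks(rep(0.7, 10)), integer(0))  # plateau
  expect_equal(detect_peaks(c(1, 2)), integer(0))       # too short
  # plateau at the top is not a strict maximum
  expect_equal(detect_peaks(c(0, 1, 1, 0)), integer(0))
})

test_that("descriptors match hand computation", {
  x <- c(0, 1, 0, 0.9, 0, 0.5, 0)
  d <- compute_descriptors(x, c(2L, 4L))
  expect_equal(d$n_peaks, 2)
  expect_equal(d$mean_peak_intensity, 0.95)
  expect_equal(d$mean_intensity, 2.4 / 7, tolerance = 1e-6)
  expect_equal(d$std_intensity, 0.420398, tolerance = 1e-5)
  # no peaks -> zero mean peak intensity
  d2 <- compute_descriptors(c(0, 1), integer(0))
  expect_equal(d2$mean_peak_intensity, 0)
  expect_equal(d2$mean_intensity, 0.5)
  expect_equal(d2$std_intensity, 0.5)  # population divisor N
  d3 <- compute_descriptors(rep(3, 8), integer(0))
  expect_equal(d3$mean_intensity, 3)
  expect_equal(d3$std_intensity, 0)
})

test_that("feature vectors have the fixed N + 4 layout", {
  fv <- assemble_feature_vector(c(0.4, 0.6),
                                list(n_peaks = 2, mean_peak_intensity = 0.95,
                                     mean_intensity = 0.5,
                                     std_intensity = 0.1))
  expect_equal(fv, c(0.4, 0.6, 2, 0.95, 0.5, 0.1))
  tf <- tiny_featurized()
  n_ch <- length(tf$records[[1]]$wavelengths)
  expect_equal(ncol(tf$features), n_ch + 4)
})

test_that("preprocessing is pure and training values stay in range", {
  tf <- tiny_featurized()
  rec <- tf$records[[3]]
  expect_identical(feature_vector(rec, tf$scaler),
                   feature_vector(rec, tf$scaler))
  for (rec in tf$records[c(1, 10, 20)]) {
    ln <- apply_scaler(rec$wavelengths, tf$scaler)
    int <- apply_scaler(rec$intensities, tf$scaler)
    expect_true(all(ln >= 0 & ln <= 1 + 1e-9))
    expect_true(all(int >= 0 & int <= 1 + 1e-9))
    expect_true(all(fuse_signature(ln, int) >= 0 &
                      fuse_signature(ln, int) <= 2))
  }
})

test_that("scaler JSON round-trips", {
  tf <- tiny_featurized()
  path <- tempfile(fileext = ".json")
  write_scaler(tf$scaler, path)
  back <- read_scaler(path)
  expect_equal(back$v_min, tf$scaler$v_min)
  expect_equal(back$v_max, tf$scaler$v_max)
  expect_equal(back$epsilon, tf$scaler$epsilon)
})

test_that("per-vector scaling mode scales each axis by its own extrema", {
  r <- make_rec(seq(200, 550, length.out = 20), seq(5, 80, length.out = 20))
  s <- fit_global_scaler(list(r), mode = "per_vector")
  expect_equal(apply_scaler(550, s, which = "lambda"), 1, tolerance = 1e-10)
  expect_equal(apply_scaler(80, s, which = "intensity"), 1,
               tolerance = 1e-10)
})
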