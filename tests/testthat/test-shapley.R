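test_that("linear models receive their main effects", {
  f <- function(X) 2 * X[, 1] + 0 * X[, 2]
  sh <- shapley_attribution(f, c(1, 1), c(0, 0), mode = "exact")
  expect_equal(unname(sh$phi[, 1]), c(2, 0))
  expect_equal(sh$phi0 + sum(sh$phi), sh$fx)
})

test_that("efficiency holds on arbitrary models and multi-output scores", {
  set.seed(31)
  f <- function(X) cbind(s1 = X[, 1] * X[, 2] - X[, 3]^2,
                         s2 = exp(X[, 1] / 3) + X[, 3])
  inst <- runif(3)
  bg <- runif(3)
  ex <- shapley_attribution(f, inst, bg, mode = "exact")
  expect_equal(unname(ex$phi0 + colSums(ex$phi)), unname(ex$fx),
               tolerance = 1e-12)
  sm <- shapley_attribution(f, inst, bg, mode = "sampled", n_samples = 500,
                            seed = 3)
  expect_equal(unname(sm$phi0 + colSums(sm$phi)), unname(sm$fx),
               tolerance = 1e-8)
})

test_that("symmetric features receive equal attribution", {
  f <- function(X) X[, 1] + X[, 2] + 3 * X[, 1] * X[, 2]
  sh <- shapley_attribution(f, c(1, 1), c(0, 0), mode = "exact")
  expect_equal(unname(sh$phi[1, 1]), unname(sh$phi[2, 1]),
               tolerance = 1e-12)
})

test_that("sampled mode with the full coalition set matches enumeration", {
  set.seed(9)
  f <- function(X) X[, 1] * X[, 2] + 3 * X[, 3] - X[, 4] * X[, 5]^2
  inst <- runif(5)
  bg <- runif(5)
  ex <- shapley_attribution(f, inst, bg, mode = "exact")
  sm <- shapley_attribution(f, inst, bg, mode = "sampled", n_samples = 30)
  expect_lt(max(abs(ex$phi - sm$phi)), 1e-6)
})

test_that("sampled accuracy does not degrade as the budget doubles", {
  f <- function(X) X[, 1] * X[, 2] + 3 * X[, 3] - X[, 4] * X[, 5]^2
  set.seed(12)
  inst <- runif(5)
  bg <- runif(5)
  ex <- shapley_attribution(f, inst, bg, mode = "exact")
  err <- vapply(c(8, 16, 30), function(ns) {
    mean(vapply(1:5, function(s) {
      sm <- shapley_attribution(f, inst, bg, mode = "sampled",
                                n_samples = ns, seed = s)
      max(abs(sm$phi - ex$phi))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(err) <= 1e-9))
})

test_that("exact mode enforces the coalition budget", {
  f <- function(X) rowSums(X)
  expect_error(shapley_attribution(f, numeric(16), numeric(16),
                                   mode = "exact"), "sampled")
})

test_that("top-feature selection ranks the dominant line first", {
  # one dominant, one secondary line; the dominant line's channel wins
  acq <- acquisition_spec(n_channels = 500, noise_sigma = 1,
                          baseline_coeffs = c(0, 0, 0),
                          pellet_gain_sigma = 0, pellet_offset_sigma = 0)
  lines <- rbind(emission_line("Fe", "I", 300, 5),
                 emission_line("Cr", "I", 450, 4.8))
  prof <- origin_profile("x", c(Fe = 100, Cr = 100))
  set.seed(3)
  recs <- replicate(6, render_spectrum(prof, lines, acq), simplify = FALSE)
  scaler <- fit_global_scaler(recs)
  top <- select_top_features(recs, scaler, k = 2)
  expect_length(top, 2)
  wl <- recs[[1]]$wavelengths
  expect_lt(abs(wl[top[1]] - 300), 2)
  expect_lt(abs(wl[top[2]] - 450), 2)
  # deterministic
  expect_identical(top, select_top_features(recs, scaler, k = 2))
  expect_warning(out <- select_top_features(recs, scaler, k = 50),
                 "peak channels")
  expect_lt(length(out), 50)
})

test_that("the default reduced representation keeps ten channels", {
  expect_equal(eval(formals(select_top_features)$k), 10)
})
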