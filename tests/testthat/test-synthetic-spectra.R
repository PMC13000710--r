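test_that("default line library contains the printed analytical lines", {
  lines <- default_line_library()
  has_line <- function(el, st, wl)
    any(lines$element == el & lines$stage == st &
          abs(lines$wavelength_nm - wl) < 1e-9)
  expect_true(has_line("Fe", "II", 247.92))
  expect_true(has_line("Cr", "II", 397.96))
  expect_true(has_line("K", "II", 428.88))
  expect_true(has_line("Na", "II", 292.35))
  expect_true(has_line("Fe", "I", 393.36))
  expect_equal(sum(lines$element == "Fe" & lines$stage == "I"), 7)
  expect_equal(sum(lines$element == "Cr"), 6)
  expect_true(all(lines$emissivity > 0))
  expect_true(all(lines$wavelength_nm >= 200 & lines$wavelength_nm <= 550))
})

test_that("default origin profiles reproduce the reference concentrations", {
  profs <- default_origin_profiles()
  expect_length(profs, 4)
  byname <- setNames(profs, vapply(profs, `[[`, character(1), "origin"))
  expect_equal(byname$Kenya$concentrations[["Cr"]], 372.91)
  expect_equal(byname$Ethiopia$concentrations[["Cu"]], 1539.17)
  expect_equal(byname$Colombia$concentrations[["Na"]], 8481.90)
  expect_equal(byname$Yunnan$concentrations[["K"]], 15561426.92)
  for (p in profs) expect_true(all(p$concentrations >= 0))
})

test_that("render_spectrum follows the line + baseline + nuisance model", {
  acq <- acquisition_spec(noise_sigma = 0, baseline_coeffs = c(0, 0, 0),
                          pellet_gain_sigma = 0, pellet_offset_sigma = 0)
  lines <- default_line_library()
  # all-zero concentrations -> all-zero intensities
  zero <- origin_profile("none", setNames(numeric(3), c("Fe", "Cr", "K")))
  rec <- render_spectrum(zero, lines, acq)
  expect_true(all(rec$intensities == 0))
  # a single line reaches ~its amplitude at the centre and decays by 3 sigma
  one_line <- emission_line("Fe", "I", 400, emissivity = 2)
  prof <- origin_profile("x", c(Fe = 50))
  rec <- render_spectrum(prof, one_line, acq)
  amp <- 2 * 50
  centre <- which.min(abs(rec$wavelengths - 400))
  expect_gt(rec$intensities[centre], 0.99 * amp)
  at3s <- which.min(abs(rec$wavelengths - (400 + 3 * acq$line_sigma)))
  expect_lt(rec$intensities[at3s], 0.02 * amp)
  # element missing from the profile is treated as zero concentration
  rec2 <- render_spectrum(origin_profile("y", c(Zn = 10)), one_line, acq)
  expect_true(all(rec2$intensities == 0))
})

test_that("the default grid spans 200-550 nm with 6145 channels", {
  acq <- acquisition_spec()
  prof <- default_origin_profiles()[[1]]
  rec <- render_spectrum(prof, default_line_library(), acq)
  expect_length(rec$wavelengths, 6145)
  expect_equal(rec$wavelengths[1], 200)
  expect_equal(rec$wavelengths[6145], 550)
  expect_true(all(diff(rec$wavelengths) > 0))
})

test_that("generate_dataset yields the full factorial design, reproducibly", {
  spec <- dataset_spec(acquisition = tiny_acq(), pellets_per_origin = 2,
                       spectra_per_pellet = 3, seed = 99)
  ds <- generate_dataset(spec)
  expect_length(ds, 4 * 2 * 3)
  expect_equal(unname(table(dataset_labels(ds))), rep(6L, 4),
               ignore_attr = TRUE)
  expect_identical(ds, generate_dataset(spec))
  # pellet structure: spectra of one pellet share gain and offset, so their
  # noise-free difference would vanish; check ids are shared in blocks
  expect_length(unique(dataset_pellets(ds)), 8)
  expect_error(generate_dataset(dataset_spec(profiles = list())),
               "profile")
})

test_that("records of one pellet share the pellet gain", {
  # with zero noise, two spectra of one pellet are identical, and pellets
  # differ only through gain/offset
  acq <- tiny_acq(noise_sigma = 0, pellet_gain_sigma = 0.3,
                  pellet_offset_sigma = 50, shot_gain_sigma = 0,
                  shot_offset_sigma = 0)
  ds <- generate_dataset(dataset_spec(acquisition = acq,
                                      pellets_per_origin = 2,
                                      spectra_per_pellet = 2, seed = 3))
  pid <- dataset_pellets(ds)
  for (p in unique(pid)) {
    recs <- ds[pid == p]
    expect_identical(recs[[1]]$intensities, recs[[2]]$intensities)
  }
  # different pellets of the same origin differ
  kenya <- ds[dataset_labels(ds) == "Kenya"]
  expect_false(identical(kenya[[1]]$intensities, kenya[[3]]$intensities))
})

test_that("rendered peak height scales linearly with concentration", {
  # grid step 0.5 nm puts the 398 nm line centre exactly on a channel
  acq <- acquisition_spec(n_channels = 701, line_sigma = 1.0,
                          noise_sigma = 0, baseline_coeffs = c(0, 0, 0),
                          pellet_gain_sigma = 0, pellet_offset_sigma = 0,
                          shot_gain_sigma = 0, shot_offset_sigma = 0)
  line <- emission_line("Cr", "II", 398, emissivity = 3.5)
  concs <- c(10, 50, 100, 250, 500)
  heights <- vapply(concs, function(cc) {
    rec <- render_spectrum(origin_profile("x", c(Cr = cc)), line, acq)
    max(rec$intensities)
  }, numeric(1))
  fit <- lm(heights ~ concs)
  # slope recovers the emissivity (up to grid discretisation of the peak)
  expect_equal(unname(coef(fit)[2]), 3.5, tolerance = 1e-3)
  expect_lt(abs(coef(fit)[1]), 1e-6)
})

test_that("confounded preset nuisance dominates unsupervised structure", {
  ds <- generate_dataset(preset_dataset_spec("confounded", seed = 42,
                                             pellets_per_origin = 4,
                                             spectra_per_pellet = 6))
  X <- intensity_matrix(ds)
  y <- factor(dataset_labels(ds))
  Z <- scale(X, center = TRUE, scale = apply(X, 2, sd))
  sil <- mean(cluster::silhouette(as.integer(y), dist(Z))[, 3])
  expect_lt(sil, 0)
})
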