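test_that("band table tiles [0, Nyquist] and classification is total", {
  defs <- band_definitions(1 / (2 * TR))
  expect_equal(defs$lower_hz[1], 0)
  expect_equal(defs$upper_hz[nrow(defs)], 1 / (2 * TR))
  expect_true(all(abs(defs$upper_hz[-nrow(defs)] - defs$lower_hz[-1]) < 1e-12))
  # every frequency gets exactly one label
  fs <- seq(0, 1 / (2 * TR), length.out = 211)
  labs <- classify_bands(fs, defs)
  expect_equal(length(labs), length(fs))
  expect_true(all(labs %in% defs$band))
  expect_error(classify_bands(2, defs), "outside")
})

test_that("central frequencies map to their physiological bands", {
  expect_equal(classify_bands(0.023), "neurophysiological")
  expect_equal(classify_bands(0.000), "trend")
  expect_equal(classify_bands(0.250), "respiratory")
  expect_equal(classify_bands(0.010), "neurophysiological") # lower bound inclusive
  expect_equal(classify_bands(0.52), "vascular_cardiac")
})

test_that("neurophysiological selection keeps the 10-200 mHz modes", {
  fit <- fixture_decomp()
  # typical resting-state mode layout: trend, four neural, then physiology
  omegas <- c(0, 23, 54, 96, 156, 232, 310, 407, 521, 632) / 1000
  fake <- fit
  fake$omega_hz <- omegas
  fake$modes <- array(0, c(10, 3, 1200))
  expect_equal(select_neurophysiological(fake), 2:5)

  fake$omega_hz <- seq(0.25, 0.65, length.out = 10)
  expect_warning(sel <- select_neurophysiological(fake), "no mode")
  expect_length(sel, 0)
})

test_that("relative energy splits equally for two equal-power tones", {
  m <- tone_matrix(c(0.02, 0.10), 3)
  fit <- mvmd(t(m), dt = TR, k = 2, tau = 2.5)
  re <- relative_energy(fit)
  expect_equal(re, c(0.5, 0.5), tolerance = 0.04)
  expect_lt(abs(sum(re) - 1), 0.05)
})

test_that("a fully captured tone carries all the energy; zeroed modes carry none", {
  fit1 <- mvmd(t(tone_matrix(0.05, 1)), dt = TR, k = 1, tau = 2.5)
  expect_equal(relative_energy(fit1), 1.0, tolerance = 0.01)

  fit <- fixture_decomp()
  fit$modes[2, , ] <- 0
  expect_identical(relative_energy(fit)[2], 0)
})

test_that("bandwidth matches closed-form oracles", {
  n <- 4096
  t <- (seq_len(n) - 1) * TR
  bin <- 1 / (n * TR)
  # delta-like spectrum: a pure tone at an exact bin frequency
  f0 <- 210 * bin
  expect_lt(spectral_bandwidth(cos(2 * pi * f0 * t), TR), 2 * bin)
  # two point masses separated by 0.02 Hz -> bandwidth 0.02
  x2 <- cos(2 * pi * 0.04 * t) + cos(2 * pi * 0.06 * t)
  expect_gte(spectral_bandwidth(x2, TR), 0.018)
  expect_equal(spectral_bandwidth(x2, TR), 0.02, tolerance = 0.01)
  # flat spectrum on [0, Nyquist]: uniform second moment, BW = Nyq/sqrt(3)
  set.seed(1)
  nyq <- 1 / (2 * TR)
  bw_noise <- mean(replicate(5, spectral_bandwidth(rnorm(n), TR)))
  expect_equal(bw_noise, nyq / sqrt(3), tolerance = 0.2)
  # zero energy
  expect_warning(bw0 <- spectral_bandwidth(numeric(128), TR), "zero-energy")
  expect_identical(bw0, 0)
})

test_that("band profile combines frequency, bandwidth, energy and labels", {
  fit <- fixture_decomp()
  bp <- band_profile(fit)
  expect_s3_class(bp, "tbl_df")
  expect_equal(bp$mode, 1:2)
  expect_equal(bp$band, c("neurophysiological", "neurophysiological"))
  expect_true(all(bp$rel_energy >= 0 & bp$rel_energy <= 1))
  expect_true(all(bp$bandwidth_hz >= 0))
  expect_identical(tidy(fit), bp)
})
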