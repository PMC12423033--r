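test_that("canonical HRF has the expected shape", {
  h <- canonical_hrf(dt = TR)
  tt <- (seq_along(h) - 1) * TR
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  peak_t <- tt[which.max(h)]
  expect_gte(peak_t, 4)
  expect_lte(peak_t, 6)
  # undershoot: negative, bounded by the double-gamma amplitude ratio
  expect_lt(min(h), 0)
  expect_gte(min(h), -0.35)
  undershoot_t <- tt[which.min(h)]
  expect_gt(undershoot_t, 10)
  expect_error(canonical_hrf(dt = 0), "positive")
})

test_that("block regressor follows boxcar-convolved-with-HRF behavior", {
  n <- 400
  expect_equal(block_regressor(numeric(0), 12, n, TR), numeric(n))

  reg <- block_regressor(60, 12, n, TR)
  tt <- (seq_len(n) - 1) * TR
  expect_true(all(reg[tt < 60] == 0))
  expect_gte(tt[which.max(reg)], 65) # peak at least 5 s after onset
  expect_equal(max(reg), 1)

  # linearity for non-overlapping blocks (up to the common normalization)
  both <- block_regressor(c(40, 180), 12, n, TR)
  a <- block_regressor(40, 12, n, TR)
  b <- block_regressor(180, 12, n, TR)
  expect_equal(both, a + b, tolerance = 1e-10)

  expect_error(block_regressor(400 * TR + 1, 12, n, TR), "within the record")
})

test_that("planted components appear at their frequencies in the FFT", {
  spec <- synthetic_spec(
    n_participants = 1, n_rois = 6, n_time = 512, n_modules = 2,
    components = list(component_spec("neural_oscillation", 0.1,
                                     jitter_freq = 0)),
    noise_sd = 0, seed = 5
  )
  cohort <- generate_cohort(spec)
  x <- cohort$signals[[1]]$data
  f_axis <- (seq_len(512) - 1) / (512 * TR)
  bin <- f_axis[2]
  for (cc in which(abs(cohort$truth$loadings[[1]][1, ]) > 0)) {
    pw <- Mod(fft(x[cc, ]))^2
    half <- seq_len(256)
    expect_lt(abs(f_axis[half][which.max(pw[half])] - 0.1), bin + 1e-12)
  }
})

test_that("cohort generation is deterministic and mean-centered", {
  spec <- default_cohort_spec(seed = 21, n_participants = 2, n_rois = 8,
                              n_time = 256)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$signals[[1]]$data, b$signals[[1]]$data)
  expect_identical(a$truth$participant_freq, b$truth$participant_freq)
  expect_lt(max(abs(rowMeans(a$signals[[2]]$data))), 1e-10)
})

test_that("module-structured loadings plant block connectivity", {
  spec <- synthetic_spec(
    n_participants = 1, n_rois = 8, n_time = 256, n_modules = 2,
    components = list(component_spec("neural_oscillation", 0.05,
                                     modules_loaded = c(1, 2))),
    noise_sd = 0, seed = 9
  )
  cohort <- generate_cohort(spec)
  truth_fc <- cohort$truth$band_fc[[1]]
  # single shared waveform: |r| = 1 everywhere, sign follows module signs
  emp <- fc_matrix(cohort$signals[[1]]$data)
  expect_equal(abs(emp), matrix(1, 8, 8), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(sign(emp[1, 5]), truth_fc[1, 5]) # cross-module sign
  expect_equal(unname(truth_fc[1, 2]), 1)       # within-module
})

test_that("frequencies above Nyquist are refused unless aliasing is requested", {
  mk <- function(alias) {
    synthetic_spec(
      n_participants = 1, n_rois = 4, n_time = 128, n_modules = 1,
      components = list(component_spec("cardiac", 1.0, allow_alias = alias)),
      seed = 1
    )
  }
  expect_error(mk(FALSE), "Nyquist")
  expect_warning(sp <- mk(TRUE), "aliased")
  expect_lt(sp$components[[1]]$center_freq_hz, 1 / (2 * TR))
})

test_that("component band consistency is validated", {
  expect_error(
    synthetic_spec(
      n_participants = 1, n_rois = 4, n_time = 128, n_modules = 1,
      components = list(component_spec("neural_oscillation", 0.3)),
      seed = 1
    ),
    "expected 'neurophysiological'"
  )
  expect_error(component_spec("neural_oscillation"), "center_freq_hz")
  expect_error(component_spec("task_block"), "block_onsets")
})
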