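test_that("two well-separated tones are recovered at their FFT-peak frequencies", {
  m <- tone_matrix(c(0.02, 0.10), 3)
  # oracle: the two largest FFT power peaks of the input
  pw <- Mod(fft(m[1, ]))^2
  f_axis <- (seq_along(pw) - 1) / (length(pw) * TR)
  half <- f_axis <= 1 / (2 * TR)
  peaks <- sort(f_axis[half][order(pw[half], decreasing = TRUE)[1:2]])

  fit <- mvmd(t(m), dt = TR, k = 2, alpha = 1000, tau = 2.5)
  expect_equal(fit$omega_hz, peaks, tolerance = 0.05)
  expect_lt(abs(fit$omega_hz[1] - 0.02) / 0.02, 0.05)
  expect_lt(abs(fit$omega_hz[2] - 0.10) / 0.10, 0.05)
})

test_that("a single pure tone is reproduced by a K = 1 decomposition", {
  m <- tone_matrix(0.05, 1)
  fit <- mvmd(t(m), dt = TR, k = 1, tau = 2.5)
  interior <- 60:1140
  err <- sqrt(sum((m[1, interior] - fit$modes[1, 1, interior])^2) /
                sum(m[1, interior]^2))
  expect_lt(err, 1e-2)
  expect_lt(abs(fit$omega_hz - 0.05) / 0.05, 0.01)
})

test_that("decomposition is bitwise deterministic for a fixed seed", {
  m <- tone_matrix(c(0.03, 0.12), 2, n = 600)
  run <- function() {
    mvmd(t(m), dt = TR, k = 2, init = "random", seed = 11)
  }
  a <- run()
  b <- run()
  expect_identical(a$omega_hz, b$omega_hz)
  expect_identical(a$modes, b$modes)
})

test_that("parameter validation and preconditions are enforced", {
  m <- tone_matrix(0.05, 1, n = 64)
  expect_error(mvmd_params(k = 0), "positive integer")
  expect_error(mvmd_params(alpha = -5), "alpha")
  expect_error(mvmd_params(tol = 0), "tol")
  expect_error(mvmd(t(m), dt = TR, k = 20), "too large")
})

test_that("mode sum plus residual reproduces the input to machine precision", {
  m <- tone_matrix(c(0.02, 0.10), 3)
  fit <- mvmd(t(m), dt = TR, k = 2, tau = 2.5)
  rec <- reconstruct(fit)
  expect_lt(sqrt(sum((m - rec)^2) / sum(m^2)), 1e-2)
  expect_lt(max(abs(m - (rec + fit$residual))), 1e-12 * max(abs(m)))
  # all-zero modes reconstruct to the zero matrix
  fit0 <- fit
  fit0$modes[] <- 0
  expect_equal(reconstruct(fit0), matrix(0, 3, 1200), ignore_attr = TRUE)
})

test_that("central frequencies are ascending and within [0, Nyquist]", {
  for (fpair in list(c(0.015, 0.08), c(0.05, 0.3), c(0.1, 0.45))) {
    fit <- mvmd(t(tone_matrix(fpair, 2, n = 800)), dt = TR, k = 2, tau = 2.5)
    expect_false(is.unsorted(fit$omega_hz))
    expect_true(all(fit$omega_hz >= 0 & fit$omega_hz <= 1 / (2 * TR)))
  }
})

test_that("C = 1 decomposition matches the independent univariate oracle", {
  x <- two_tone(0.025, 0.11, n = 800)
  x <- x - mean(x)
  orc <- vmd_oracle(x, K = 2, alpha = 1000, tau = 2.5, tol = 1e-10,
                    max_iter = 2000)
  fit <- mvmd(matrix(x, ncol = 1), dt = TR, k = 2, alpha = 1000, tau = 2.5,
              tol = 1e-10, max_iter = 2000, init = "uniform")
  expect_lt(max(abs(fit$omega_hz * TR - orc$omega)), 1e-8)
  expect_lt(max(abs(fit$modes[, 1, ] - orc$modes)), 1e-8)
})

test_that("mode energies do not exceed the input energy on clean fixtures", {
  m <- tone_matrix(c(0.02, 0.10), 3)
  fit <- mvmd(t(m), dt = TR, k = 2, tau = 2.5)
  expect_lt(sum(fit$modes^2), sum(m^2) * 1.05)
})

test_that("a 10x larger alpha does not widen any recovered mode", {
  m <- tone_matrix(c(0.02, 0.10), 2)
  bw <- function(alpha) {
    fit <- mvmd(t(m), dt = TR, k = 2, alpha = alpha, tau = 2.5)
    mode_bandwidth(fit)
  }
  expect_true(all(bw(10000) <= bw(1000) + 1e-12))
})

test_that("permuting channels permutes mode channels and leaves omega unchanged", {
  set.seed(42)
  t <- (0:799) * TR
  m <- rbind(cos(2 * pi * 0.02 * t) + 0.5 * cos(2 * pi * 0.1 * t),
             0.8 * cos(2 * pi * 0.02 * t + 1) - cos(2 * pi * 0.1 * t),
             0.3 * cos(2 * pi * 0.02 * t) + cos(2 * pi * 0.1 * t + 2))
  perm <- c(3, 1, 2)
  f1 <- mvmd(t(m), dt = TR, k = 2, tau = 2.5)
  f2 <- mvmd(t(m[perm, ]), dt = TR, k = 2, tau = 2.5)
  expect_lt(max(abs(f1$omega_hz - f2$omega_hz)), 1e-10)
  expect_lt(max(abs(f1$modes[, perm, ] - f2$modes)), 1e-10)
})

test_that("degenerate constant input warns and yields near-DC modes", {
  m <- matrix(3.2, 2, 64)
  w <- capture_warnings(fit <- mvmd(t(m), dt = TR, k = 2))
  expect_true(any(grepl("constant", w)))
  expect_true(all(fit$omega_hz < 0.02))
})

test_that("instantaneous attributes of a recovered mode match the planted tone", {
  fit <- fixture_decomp()
  ia <- instantaneous_attributes(fit$modes[2, , ], dt = TR)
  interior <- 100:1100
  expect_equal(mean(ia$frequency_hz[1, interior]), 0.10, tolerance = 0.02)
})
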