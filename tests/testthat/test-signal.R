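test_that("mv_signal centers channels and validates input", {
  ts <- tibble::tibble(a = rnorm(100) + 5, b = rnorm(100) - 3)
  sig <- mv_signal(ts, dt = TR)
  expect_s3_class(sig, "mv_signal")
  expect_equal(dim(sig$data), c(2, 100))
  expect_lt(max(abs(rowMeans(sig$data))), 1e-10)
  expect_equal(sig$channel_labels, c("a", "b"))

  uncentered <- mv_signal(ts, dt = TR, center = FALSE)
  expect_equal(unname(uncentered$data[1, ]), ts$a)

  expect_error(mv_signal(ts, dt = -1), "dt")
  expect_error(mv_signal(tibble::tibble(a = c(1, NA, 3, 4, 5, 6, 7, 8)),
                         dt = TR), "non-finite")
  expect_error(mv_signal(tibble::tibble(a = 1:5), dt = TR), "8 time points")
})

test_that("analytic signal preserves the real part and kills negative frequencies", {
  z0 <- analytic_signal(rep(0, 64))
  expect_equal(z0, complex(real = rep(0, 64), imaginary = rep(0, 64)))

  x <- rnorm(501) # odd length path
  z <- analytic_signal(x)
  expect_equal(Re(z), x)
  # negative-frequency half of the spectrum is (numerically) empty
  sp <- fft(z)
  neg <- sp[((length(x) + 1) %/% 2 + 1):length(x)]
  expect_lt(max(Mod(neg)) / max(Mod(sp)), 1e-10)

  expect_error(analytic_signal(c(1, NaN, 3)), "non-finite")
})

test_that("analytic signal of a cosine is the sine quadrature pair", {
  n <- 1024
  t <- (seq_len(n) - 1) * TR
  x <- cos(2 * pi * 0.1 * t)
  z <- analytic_signal(x)
  interior <- seq(ceiling(0.05 * n), floor(0.95 * n))
  expect_lt(max(abs(Im(z)[interior] - sin(2 * pi * 0.1 * t)[interior])), 0.05)
})

test_that("instantaneous attributes recover a pure tone's amplitude and frequency", {
  n <- 1000
  t <- (seq_len(n) - 1) * TR
  A <- 1.7
  f <- 0.05
  ia <- instantaneous_attributes(A * cos(2 * pi * f * t), dt = TR)
  interior <- 100:900
  expect_lt(max(abs(ia$amplitude[1, interior] - A)) / A, 0.02)
  expect_lt(max(abs(ia$frequency_hz[1, interior] - f)) / f, 0.02)
})

test_that("instantaneous attributes handle zero modes and chirps", {
  ia <- instantaneous_attributes(matrix(0, 2, 100), dt = TR)
  expect_true(all(ia$amplitude == 0))
  expect_true(all(ia$frequency_hz == 0)) # frequency of silence is 0 by convention

  # slowly increasing chirp: the smoothed frequency estimate trends up
  # monotonically (block means strictly increase; residual quadrature
  # ripple of the discrete estimator stays below 5e-4 Hz per step)
  n <- 2000
  t <- (seq_len(n) - 1) * TR
  f0 <- 0.02
  rate <- 0.05 / (n * TR) # 0.02 -> 0.07 Hz over the record
  x <- cos(2 * pi * (f0 * t + rate * t^2 / 2))
  ia <- instantaneous_attributes(x, dt = TR)
  interior <- 100:(n - 100)
  sm <- stats::filter(ia$frequency_hz[1, interior], rep(1 / 5, 5))
  sm <- sm[!is.na(sm)]
  blocks <- colMeans(matrix(sm[1:(90 * floor(length(sm) / 90))], nrow = 90))
  expect_true(all(diff(blocks) > 0))
  expect_gt(min(diff(sm)), -5e-4)

  expect_error(instantaneous_attributes(matrix(1, 1, 3), dt = TR), "4 samples")
})
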