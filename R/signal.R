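#' Construct a multivariate ROI time-series object
#'
#' Bundles one participant's region-of-interest (ROI) time series with its
#' sampling interval. The natural input is a data frame as read from a
#' parcellated fMRI export: one row per time point, one column per ROI,
#' column names carrying the ROI labels. Internally the series is stored as
#' a channels-by-time matrix.
#'
#' Each channel is mean-centered on construction (the conventional first
#' step for ROI series, so that near-DC content reflects drift rather than
#' baseline offset). Disable with `center = FALSE`.
#'
#' @param x A data frame or tibble (rows = time points, columns = ROIs), or
#'   a numeric matrix. A matrix is interpreted as channels x time when it
#'   has row names or when `byrow = TRUE`; a plain T x C matrix can be
#'   passed as a data frame.
#' @param dt Sampling interval (repetition time) in seconds, e.g. 0.72.
#' @param channel_labels Optional character vector of ROI labels; defaults
#'   to the column names of `x`.
#' @param participant_id Optional identifier stored with the object.
#' @param center Mean-center each channel (default `TRUE`).
#' @param byrow For matrix input, set `TRUE` if rows are channels.
#'
#' @return An object of class `mv_signal` with fields `data` (C x T
#'   matrix), `dt`, `channel_labels`, `participant_id`.
#' @examples
#' ts <- tibble::tibble(roiA = rnorm(128), roiB = rnorm(128))
#' sig <- mv_signal(ts, dt = 0.72)
#' sig
#' @export
mv_signal <- function(x, dt, channel_labels = NULL, participant_id = NULL,
                      center = TRUE, byrow = FALSE) {
  if (is.data.frame(x)) {
    if (is.null(channel_labels)) channel_labels <- names(x)
    x <- t(as.matrix(x))
  } else if (is.matrix(x)) {
    if (!byrow) x <- t(x)
    if (is.null(channel_labels)) channel_labels <- rownames(x)
  } else if (is.numeric(x)) {
    x <- matrix(x, nrow = 1)
  } else {
    stop_modefc("`x` must be a data frame, matrix or numeric vector")
  }
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)
    stop_modefc(
      "non-finite values in the time series (first at channel ",
      bad[1, 1], ", sample ", bad[1, 2], ")"
    )
  }
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop_modefc("`dt` must be a single positive number (seconds)")
  }
  if (ncol(x) < 8L) stop_modefc("need at least 8 time points, got ", ncol(x))
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ROI", seq_len(nrow(x)))
  }
  if (length(channel_labels) != nrow(x)) {
    stop_modefc("channel_labels length (", length(channel_labels),
                ") does not match channel count (", nrow(x), ")")
  }
  if (center) x <- x - rowMeans(x)
  dimnames(x) <- list(channel_labels, NULL)
  structure(
    list(data = x, dt = dt, channel_labels = as.character(channel_labels),
         participant_id = participant_id),
    class = "mv_signal"
  )
}

#' @export
print.mv_signal <- function(x, ...) {
  cat("<mv_signal> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples, dt = ", x$dt, " s (Nyquist ",
      format(1000 / (2 * x$dt), digits = 4), " mHz)\n", sep = "")
  if (!is.null(x$participant_id)) cat("participant:", x$participant_id, "\n")
  invisible(x)
}

#' @method as_tibble mv_signal
#' @export
as_tibble.mv_signal <- function(x, ...) {
  tibble::as_tibble(t(x$data)) |>
    dplyr::mutate(time = (dplyr::row_number() - 1) * x$dt, .before = 1) |>
    tidyr::pivot_longer(-"time", names_to = "roi", values_to = "value")
}

nyquist_hz <- function(dt) 1 / (2 * dt)

#' Discrete analytic signal via the Hilbert transform
#'
#' Returns the complex analytic extension of a real series: the real part
#' is the input, the imaginary part its discrete Hilbert transform, and the
#' spectrum is (up to the DC and Nyquist bins) one-sided. Computed by
#' doubling the positive-frequency half of the FFT.
#'
#' @param x Real numeric vector, length >= 2.
#' @return Complex vector of the same length.
#' @examples
#' t <- seq(0, 50, by = 0.1)
#' z <- analytic_signal(cos(2 * pi * 0.4 * t))
#' all.equal(Re(z), cos(2 * pi * 0.4 * t))
#' @export
analytic_signal <- function(x) {
  if (!is.numeric(x) || length(x) < 2L) {
    stop_modefc("`x` must be a numeric vector of length >= 2")
  }
  if (!all(is.finite(x))) stop_modefc("non-finite values in `x`")
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- fft(fft(x) * h, inverse = TRUE) / n
  complex(real = x, imaginary = Im(z))
}

#' Instantaneous amplitude and frequency of a mode
#'
#' Per-channel amplitude envelope (modulus of the analytic signal) and
#' instantaneous frequency (phase increment of the analytic signal, scaled
#' to Hz and clipped to `[0, Nyquist]`). A channel that is identically zero
#' reports amplitude 0 and, by convention, frequency 0.
#'
#' The frequency at sample `t` is derived from the wrapped phase difference
#' between samples `t` and `t + 1`; the last sample repeats the previous
#' estimate so both outputs keep the input's dimensions.
#'
#' @param mode Numeric matrix, channels x time (a single mode's waveforms),
#'   or a numeric vector for one channel.
#' @param dt Sampling interval in seconds.
#' @return A list with `amplitude` and `frequency_hz`, both channels x time.
#' @examples
#' t <- (0:999) * 0.72
#' ia <- instantaneous_attributes(2 * cos(2 * pi * 0.05 * t), dt = 0.72)
#' mean(ia$amplitude[1, 100:900])   # ~2
#' mean(ia$frequency_hz[1, 100:900]) # ~0.05
#' @export
instantaneous_attributes <- function(mode, dt) {
  if (is.numeric(mode) && !is.matrix(mode)) mode <- matrix(mode, nrow = 1)
  if (!is.matrix(mode) || !is.numeric(mode)) {
    stop_modefc("`mode` must be a numeric matrix (channels x time)")
  }
  if (ncol(mode) < 4L) stop_modefc("need at least 4 samples per channel")
  nyq <- nyquist_hz(dt)
  amp <- matrix(0, nrow(mode), ncol(mode))
  freq <- matrix(0, nrow(mode), ncol(mode))
  for (cc in seq_len(nrow(mode))) {
    if (all(mode[cc, ] == 0)) next # zero channel: amplitude 0, frequency 0
    z <- analytic_signal(mode[cc, ])
    amp[cc, ] <- Mod(z)
    dphi <- Arg(z[-1] * Conj(z[-length(z)]))
    f <- dphi / (2 * pi * dt)
    freq[cc, ] <- pmin(pmax(c(f, f[length(f)]), 0), nyq)
  }
  dimnames(amp) <- dimnames(mode)
  dimnames(freq) <- dimnames(mode)
  list(amplitude = amp, frequency_hz = freq)
}
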