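#' Physiological frequency bands for fMRI time series
#'
#' Default band table used to label intrinsic modes by their central
#' frequency: near-DC trend/drift below 10 mHz; the neurophysiological band
#' at 10-200 mHz where BOLD fluctuations of neural origin dominate;
#' respiration around its ~250 mHz fundamental; vascular/cardiac content in
#' the 350-800 mHz range (cardiac first harmonic ~520 mHz); anything above
#' is `other_high`. Bands are half-open, lower-bound inclusive, truncated
#' at the Nyquist frequency (bands entirely above Nyquist are dropped), so
#' the table always partitions `[0, Nyquist]`.
#'
#' @param nyquist_hz Upper edge of the spectrum in Hz; `1 / (2 * dt)`. The
#'   default corresponds to a 0.72 s repetition time.
#' @return A tibble with columns `band`, `lower_hz`, `upper_hz`.
#' @examples
#' band_definitions()
#' @export
band_definitions <- function(nyquist_hz = 1 / (2 * 0.72)) {
  if (!is.numeric(nyquist_hz) || nyquist_hz <= 0) {
    stop_modefc("`nyquist_hz` must be positive")
  }
  defs <- tibble::tibble(
    band = c("trend", "neurophysiological", "respiratory",
             "vascular_cardiac", "other_high"),
    lower_hz = c(0, 0.010, 0.200, 0.350, 0.800),
    upper_hz = c(0.010, 0.200, 0.350, 0.800, Inf)
  )
  defs <- defs[defs$lower_hz < nyquist_hz, ]
  defs$upper_hz <- pmin(defs$upper_hz, nyquist_hz)
  defs$upper_hz[nrow(defs)] <- nyquist_hz
  defs
}

validate_band_definitions <- function(defs) {
  need <- c("band", "lower_hz", "upper_hz")
  if (!is.data.frame(defs) || !all(need %in% names(defs))) {
    stop_modefc("band definitions need columns band, lower_hz, upper_hz")
  }
  if (any(defs$lower_hz >= defs$upper_hz)) stop_modefc("empty band in definitions")
  if (nrow(defs) > 1) {
    o <- order(defs$lower_hz)
    if (any(abs(defs$upper_hz[o][-nrow(defs)] - defs$lower_hz[o][-1]) > 1e-12)) {
      stop_modefc("band definitions must tile the axis without gaps or overlap")
    }
  }
  defs
}

#' Classify central frequencies into physiological bands
#'
#' Maps each frequency to the unique band covering it (bands are
#' lower-inclusive, upper-exclusive; the top band includes its upper edge
#' so classification is total on `[0, Nyquist]`).
#'
#' @param freq_hz Numeric vector of central frequencies in Hz.
#' @param defs Band table from [band_definitions()].
#' @return Character vector of band labels, same length as `freq_hz`.
#' @examples
#' classify_bands(c(0, 0.023, 0.25))
#' @export
classify_bands <- function(freq_hz, defs = band_definitions()) {
  defs <- validate_band_definitions(defs)
  defs <- defs[order(defs$lower_hz), ]
  top <- nrow(defs)
  vapply(freq_hz, function(f) {
    if (!is.finite(f) || f < defs$lower_hz[1] || f > defs$upper_hz[top]) {
      stop_modefc("frequency ", f, " Hz is outside the band table [",
                  defs$lower_hz[1], ", ", defs$upper_hz[top], "]")
    }
    i <- findInterval(f, defs$lower_hz)
    defs$band[i]
  }, character(1))
}

#' Relative energy of each mode
#'
#' The energy ratio \eqn{E_k / E_{tot}} with
#' \eqn{E_k = \sum_c \sum_t u_{k,c}(t)^2} and \eqn{E_{tot}} the energy of
#' the analyzed signal (mode sum plus residual). Low-frequency modes of
#' resting fMRI typically dominate this ranking.
#'
#' @param ms An [mvmd_decomp] object.
#' @return Numeric vector of length `k`, nonnegative.
#' @export
relative_energy <- function(ms) {
  if (!inherits(ms, "mvmd_decomp")) stop_modefc("`ms` must be an mvmd_decomp")
  x <- reconstruct(ms) + ms$residual
  e_tot <- sum(x^2)
  if (e_tot == 0) stop_modefc("zero-energy input signal")
  apply(ms$modes, 1, function(m) sum(m^2)) / e_tot
}

# channel-summed power spectrum of one mode on the nonnegative frequency axis
mode_power_spectrum <- function(m, dt) {
  n_time <- ncol(m)
  sp <- mvfft(t(m))
  pw <- rowSums(Mod(sp)^2)
  n_pos <- floor(n_time / 2) + 1L
  tibble::tibble(
    freq_hz = (seq_len(n_pos) - 1) / (n_time * dt),
    power = pw[seq_len(n_pos)]
  )
}

#' Spectral bandwidth of a waveform matrix
#'
#' Twice the root of the power-weighted second central moment of the
#' channel-summed power spectrum about its spectral centroid (an RMS
#' bandwidth; the factor 2 makes a symmetric two-point spectrum with
#' separation `d` report bandwidth `d`). Zero-energy input reports 0 with
#' a warning.
#'
#' @param m Numeric matrix (channels x time) or vector.
#' @param dt Sampling interval in seconds.
#' @return Bandwidth in Hz.
#' @export
spectral_bandwidth <- function(m, dt) {
  if (is.numeric(m) && !is.matrix(m)) m <- matrix(m, nrow = 1)
  ps <- mode_power_spectrum(m, dt)
  tot <- sum(ps$power)
  if (tot == 0) {
    warning("zero-energy waveform; bandwidth reported as 0", call. = FALSE)
    return(0)
  }
  mu <- sum(ps$freq_hz * ps$power) / tot
  2 * sqrt(sum((ps$freq_hz - mu)^2 * ps$power) / tot)
}

#' Spectral bandwidth of a mode
#'
#' Applies [spectral_bandwidth()] to each requested mode of a
#' decomposition.
#'
#' @param ms An [mvmd_decomp] object.
#' @param k Mode index or vector of indices; default all modes.
#' @return Numeric vector of bandwidths in Hz.
#' @export
mode_bandwidth <- function(ms, k = NULL) {
  if (!inherits(ms, "mvmd_decomp")) stop_modefc("`ms` must be an mvmd_decomp")
  if (is.null(k)) k <- seq_len(dim(ms$modes)[1])
  vapply(k, function(ki) spectral_bandwidth(mode_matrix(ms, ki), ms$dt),
         numeric(1))
}

#' Per-mode band profile
#'
#' One row per mode: central frequency, RMS bandwidth, relative energy and
#' physiological band label — the summary table used to decide which modes
#' carry neurophysiological signal.
#'
#' @param ms An [mvmd_decomp] object.
#' @param defs Band table from [band_definitions()]; defaults to the table
#'   for this decomposition's Nyquist frequency.
#' @return A tibble with columns `mode`, `central_freq_hz`, `bandwidth_hz`,
#'   `rel_energy`, `band`.
#' @export
band_profile <- function(ms, defs = NULL) {
  if (!inherits(ms, "mvmd_decomp")) stop_modefc("`ms` must be an mvmd_decomp")
  if (is.null(defs)) defs <- band_definitions(nyquist_hz(ms$dt))
  tibble::tibble(
    mode = seq_along(ms$omega_hz),
    central_freq_hz = ms$omega_hz,
    bandwidth_hz = mode_bandwidth(ms),
    rel_energy = relative_energy(ms),
    band = classify_bands(ms$omega_hz, defs)
  )
}

#' Indices of modes in the neurophysiological band
#'
#' Selects the modes whose central frequency falls in the
#' neurophysiological band (10-200 mHz by default) — the band-selection
#' step between decomposition and connectivity estimation.
#'
#' @inheritParams band_profile
#' @return Ascending integer vector of mode indices; empty (with a
#'   warning) when no mode lies in the band.
#' @examples
#' \donttest{
#' t <- (0:599) * 0.72
#' fit <- mvmd(data.frame(a = cos(2 * pi * 0.05 * t)), dt = 0.72, k = 1)
#' select_neurophysiological(fit)
#' }
#' @export
select_neurophysiological <- function(ms, defs = NULL) {
  if (is.null(defs)) defs <- band_definitions(nyquist_hz(ms$dt))
  labs <- classify_bands(ms$omega_hz, defs)
  idx <- which(labs == "neurophysiological")
  if (length(idx) == 0) {
    warning("no mode has its central frequency in the neurophysiological band",
            call. = FALSE)
  }
  sort(idx)
}
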