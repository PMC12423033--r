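#' Canonical double-gamma hemodynamic response function
#'
#' The conventional canonical HRF: a gamma density peaking ~5 s after the
#' event minus a scaled, later gamma density producing the post-stimulus
#' undershoot around 15 s. Sampled at `dt` and peak-normalized to 1; the
#' kernel is 0 at `t = 0`.
#'
#' @param dt Sampling interval in seconds.
#' @param duration Kernel length in seconds (default 32, by which time the
#'   response has returned to baseline).
#' @param peak_delay,undershoot_delay Shape parameters (seconds) of the
#'   response and undershoot gamma densities; defaults 6 and 16.
#' @param dispersion,u_dispersion Scale (seconds) of the two densities.
#' @param ratio Undershoot amplitude relative to the response (default 1/6).
#' @return Numeric vector of kernel samples at `0, dt, 2 dt, ...`.
#' @examples
#' h <- canonical_hrf(dt = 0.72)
#' (which.max(h) - 1) * 0.72 # peak time, ~5 s
#' @export
canonical_hrf <- function(dt, duration = 32, peak_delay = 6,
                          undershoot_delay = 16, dispersion = 1,
                          u_dispersion = 1, ratio = 1 / 6) {
  if (!is.numeric(dt) || dt <= 0) stop_modefc("`dt` must be positive")
  t <- seq(0, duration, by = dt)
  h <- dgamma(t, shape = peak_delay / dispersion, scale = dispersion) -
    ratio * dgamma(t, shape = undershoot_delay / u_dispersion,
                   scale = u_dispersion)
  h / max(h)
}

#' Block-design regressor under the canonical HRF
#'
#' Boxcar of the given onsets and duration convolved with
#' [canonical_hrf()], truncated to the record length and peak-normalized —
#' the classical convolutional reference for a block paradigm (e.g. 12 s
#' movement blocks preceded by a 3 s cue).
#'
#' @param onsets Block onset times in seconds (may be empty).
#' @param duration Block duration in seconds.
#' @param n_time Number of samples in the record.
#' @param dt Sampling interval in seconds.
#' @param hrf Optional kernel; defaults to `canonical_hrf(dt)`.
#' @return Numeric vector of length `n_time`.
#' @export
block_regressor <- function(onsets, duration, n_time, dt, hrf = NULL) {
  if (length(onsets) == 0) return(numeric(n_time))
  if (any(onsets < 0 | onsets >= n_time * dt)) {
    stop_modefc("block onsets must lie within the record [0, ",
                round(n_time * dt, 2), ") s")
  }
  box <- numeric(n_time)
  tgrid <- (seq_len(n_time) - 1) * dt
  for (on in onsets) box[tgrid >= on & tgrid < on + duration] <- 1
  if (is.null(hrf)) hrf <- canonical_hrf(dt)
  # direct convolution (no FFT round-off: samples before the first onset
  # stay exactly zero)
  padded <- c(rep(0, length(hrf) - 1), box)
  reg <- as.numeric(stats::filter(padded, hrf, method = "convolution",
                                  sides = 1))[length(hrf) - 1 + seq_len(n_time)]
  if (max(abs(reg)) > 0) reg <- reg / max(abs(reg))
  reg
}

#' Specify one signal component of a synthetic cohort
#'
#' @param kind One of `"trend"`, `"neural_oscillation"`, `"task_block"`,
#'   `"respiratory"`, `"cardiac"`. The center frequency must be consistent
#'   with the kind's physiological band (see [band_definitions()]).
#' @param center_freq_hz Nominal center frequency in Hz (ignored for
#'   `trend` and `task_block`).
#' @param amplitude Nominal component amplitude (waveforms have unit
#'   standard deviation; loadings scale with this).
#' @param loading `"shared_modules"` plants the same module-structured
#'   loading pattern in every participant (a reproducible connectivity
#'   template); `"participant_random"` draws fresh loadings per participant
#'   (individual-specific structure, e.g. drifts and physiology).
#' @param modules_loaded For `shared_modules`: which module indices carry
#'   the component (default: all).
#' @param jitter_freq Per-participant relative center-frequency jitter
#'   (uniform, default +/-10%).
#' @param jitter_amp Per-participant relative amplitude jitter (uniform,
#'   default +/-20%).
#' @param am_depth Depth of the slow amplitude modulation applied to
#'   oscillatory components (default 0.2).
#' @param block_onsets,block_duration Task-block design (seconds), for
#'   `kind = "task_block"`.
#' @param allow_alias Permit a center frequency above Nyquist by folding it
#'   to its alias (with a warning), mimicking cardiac content aliased into
#'   lower bands; otherwise such a frequency is refused.
#' @return A `component_spec` list.
#' @export
component_spec <- function(kind = c("neural_oscillation", "trend",
                                    "task_block", "respiratory", "cardiac"),
                           center_freq_hz = NA_real_, amplitude = 1,
                           loading = c("shared_modules", "participant_random"),
                           modules_loaded = NULL, jitter_freq = 0.1,
                           jitter_amp = 0.2, am_depth = 0.2,
                           block_onsets = NULL, block_duration = NULL,
                           allow_alias = FALSE) {
  kind <- match.arg(kind)
  loading <- match.arg(loading)
  if (kind == "task_block" && (is.null(block_onsets) || is.null(block_duration))) {
    stop_modefc("task_block components need block_onsets and block_duration")
  }
  if (!kind %in% c("trend", "task_block") && !is.finite(center_freq_hz)) {
    stop_modefc(kind, " components need a finite center_freq_hz")
  }
  structure(
    list(kind = kind, center_freq_hz = center_freq_hz, amplitude = amplitude,
         loading = loading, modules_loaded = modules_loaded,
         jitter_freq = jitter_freq, jitter_amp = jitter_amp,
         am_depth = am_depth, block_onsets = block_onsets,
         block_duration = block_duration, allow_alias = allow_alias),
    class = "component_spec"
  )
}

component_band <- function(kind) {
  switch(kind,
         trend = "trend",
         neural_oscillation = "neurophysiological",
         task_block = "neurophysiological",
         respiratory = "respiratory",
         cardiac = "vascular_cardiac")
}

#' Specify a synthetic fMRI-like cohort
#'
#' Describes a cohort of multichannel series built as a sum of planted
#' components (drift, band-limited oscillations, physiological tones,
#' optionally HRF-convolved task blocks) with module-structured loadings
#' plus white noise — so that decomposition, band selection, connectivity
#' and reproducibility can all be checked against known ground truth.
#' Defaults mirror the shape of parcellated human resting-state data:
#' 90 ROIs in 7 functional modules sampled at TR = 0.72 s for 1200 frames.
#'
#' @param n_participants Cohort size.
#' @param n_rois Number of ROIs (default 90).
#' @param dt Sampling interval in seconds (default 0.72).
#' @param n_time Samples per participant (default 1200).
#' @param modules Named list of ROI index vectors partitioning
#'   `1:n_rois`; default: `n_modules` contiguous blocks of near-equal size.
#' @param n_modules Number of auto-built modules when `modules` is `NULL`.
#' @param components List of [component_spec()]s.
#' @param noise_sd Standard deviation of the additive white noise.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the spec including this seed.
#' @return A `synthetic_spec` object.
#' @seealso [default_cohort_spec()] for the evaluation cohort used
#'   throughout the package's tests.
#' @export
synthetic_spec <- function(n_participants, n_rois = 90, dt = 0.72,
                           n_time = 1200, modules = NULL, n_modules = 7,
                           components = list(), noise_sd = 1, seed = 1) {
  if (n_time < 64) stop_modefc("`n_time` must be >= 64")
  if (dt <= 0) stop_modefc("`dt` must be positive")
  if (is.null(modules)) {
    cut_idx <- sort(rep_len(seq_len(n_modules), n_rois))
    modules <- split(seq_len(n_rois), paste0("M", cut_idx))
    modules <- modules[order(vapply(modules, min, 1L))]
  }
  got <- sort(unlist(modules, use.names = FALSE))
  if (!identical(got, seq_len(n_rois))) {
    stop_modefc("`modules` must partition 1:", n_rois)
  }
  if (!all(vapply(components, inherits, TRUE, "component_spec"))) {
    stop_modefc("`components` must be component_spec objects")
  }
  nyq <- nyquist_hz(dt)
  defs <- band_definitions(nyq)
  for (i in seq_along(components)) {
    cmp <- components[[i]]
    if (cmp$kind %in% c("trend", "task_block")) next
    f <- cmp$center_freq_hz
    if (f > nyq) {
      if (!cmp$allow_alias) {
        stop_modefc("component ", i, " at ", f, " Hz exceeds Nyquist (",
                    round(nyq, 3), " Hz); set allow_alias = TRUE to fold it")
      }
      fa <- abs(((f + nyq) %% (2 * nyq)) - nyq)
      warning("component ", i, " at ", f, " Hz aliased to ",
              round(fa, 4), " Hz", call. = FALSE)
      components[[i]]$center_freq_hz <- f <- fa
    }
    want <- component_band(cmp$kind)
    gotb <- classify_bands(f, defs)
    if (gotb != want && !(cmp$kind == "cardiac" && cmp$allow_alias)) {
      stop_modefc("component ", i, " (", cmp$kind, ") at ", f,
                  " Hz falls in band '", gotb, "', expected '", want, "'")
    }
  }
  structure(
    list(n_participants = as.integer(n_participants),
         n_rois = as.integer(n_rois), dt = dt, n_time = as.integer(n_time),
         modules = modules, components = components, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' The default evaluation cohort
#'
#' The cohort used throughout the package's own validation: 10
#' participants, 20 ROIs in 4 modules, 1200 samples at TR = 0.72 s, with
#' a participant-specific random-walk trend, three shared neural
#' oscillations at 25, 60 and 110 mHz loaded on overlapping module pairs,
#' a participant-specific respiratory tone at 250 mHz, and white noise at
#' `noise_sd = 1.25`, which puts the signal-to-noise ratio near 0 dB.
#'
#' @param seed Integer seed.
#' @param n_participants,n_rois,n_time,noise_sd Overrides of the default
#'   conditions.
#' @return A `synthetic_spec`.
#' @export
default_cohort_spec <- function(seed = 1, n_participants = 10, n_rois = 20,
                                n_time = 1200, noise_sd = 1.25) {
  synthetic_spec(
    n_participants = n_participants, n_rois = n_rois, dt = 0.72,
    n_time = n_time, n_modules = 4,
    components = list(
      component_spec("trend", amplitude = 0.8, loading = "participant_random"),
      component_spec("neural_oscillation", 0.025, amplitude = 1,
                     modules_loaded = c(1, 2)),
      component_spec("neural_oscillation", 0.060, amplitude = 1,
                     modules_loaded = c(2, 3)),
      component_spec("neural_oscillation", 0.110, amplitude = 1,
                     modules_loaded = c(3, 4)),
      component_spec("respiratory", 0.250, amplitude = 0.6,
                     loading = "participant_random")
    ),
    noise_sd = noise_sd, seed = seed
  )
}

# random-walk drift low-passed below `cutoff_hz`, unit sd
trend_waveform <- function(n_time, dt, cutoff_hz = 0.008) {
  w <- cumsum(rnorm(n_time))
  sp <- fft(w)
  f <- (seq_len(n_time) - 1) / (n_time * dt)
  f <- pmin(f, 1 / dt - f) # two-sided axis
  sp[f > cutoff_hz] <- 0
  w <- Re(fft(sp, inverse = TRUE)) / n_time
  w <- w - mean(w)
  s <- sd(w)
  if (s > 0) w / s else w
}

# slow-AM tone, unit sd
tone_waveform <- function(freq_hz, n_time, dt, am_depth) {
  t <- (seq_len(n_time) - 1) * dt
  am <- 1 + am_depth * sin(2 * pi * 0.005 * t + runif(1, 0, 2 * pi))
  w <- am * sin(2 * pi * freq_hz * t + runif(1, 0, 2 * pi))
  w / sd(w)
}

# module-structured base loadings shared by all participants: alternating
# module signs, per-ROI magnitudes in [0.8, 1.2], zero off the loaded modules
shared_loadings <- function(cmp, spec) {
  l <- numeric(spec$n_rois)
  mods <- cmp$modules_loaded
  if (is.null(mods)) mods <- seq_along(spec$modules)
  for (j in seq_along(mods)) {
    idx <- spec$modules[[mods[j]]]
    l[idx] <- (-1)^(j - 1) * runif(length(idx), 0.8, 1.2)
  }
  l * cmp$amplitude
}

#' Generate a synthetic cohort with ground truth
#'
#' Realizes a [synthetic_spec()]: every participant's series is the sum
#' over components of loading x waveform — an amplitude-modulated tone
#' with per-participant frequency/amplitude jitter, an HRF-convolved block
#' regressor, or a low-passed random-walk drift — plus white noise, with
#' channels mean-centered. Deterministic for a fixed spec (including its
#' seed).
#'
#' @param spec A `synthetic_spec`.
#' @return A list with
#' \describe{
#'   \item{signals}{list of [mv_signal] objects, one per participant}
#'   \item{truth}{ground truth: per-component loading matrices
#'     (participants x ROIs), realized per-participant center frequencies,
#'     component waveforms (participants x time), and for each
#'     shared-loading component the planted connectivity matrix
#'     (`band_fc`, the correlation pattern of the noiseless component:
#'     sign of the loading product for loaded ROI pairs, 0 elsewhere)}
#' }
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(seed = 42, n_participants = 2,
#'                                               n_rois = 8, n_time = 256))
#' cohort$signals[[1]]
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    stop_modefc("`spec` must come from synthetic_spec()")
  }
  n_cmp <- length(spec$components)
  C <- spec$n_rois
  N <- spec$n_participants
  n_time <- spec$n_time
  labels <- paste0("ROI", sprintf("%02d", seq_len(C)))

  truth <- list(
    components = tibble::tibble(
      component = seq_len(n_cmp),
      kind = vapply(spec$components, `[[`, "", "kind"),
      center_freq_hz = vapply(spec$components, `[[`, 1, "center_freq_hz"),
      loading = vapply(spec$components, `[[`, "", "loading")
    ),
    loadings = vector("list", n_cmp),
    waveforms = vector("list", n_cmp),
    participant_freq = matrix(NA_real_, n_cmp, N),
    band_fc = vector("list", n_cmp)
  )

  signals <- vector("list", N)
  with_local_seed(spec$seed, {
    base_load <- vector("list", n_cmp)
    for (i in seq_len(n_cmp)) {
      cmp <- spec$components[[i]]
      truth$loadings[[i]] <- matrix(NA_real_, N, C)
      truth$waveforms[[i]] <- matrix(NA_real_, N, n_time)
      if (cmp$loading == "shared_modules") {
        base_load[[i]] <- shared_loadings(cmp, spec)
        fc <- outer(sign(base_load[[i]]), sign(base_load[[i]]))
        diag(fc) <- 1
        dimnames(fc) <- list(labels, labels)
        truth$band_fc[[i]] <- fc
      }
    }
    for (p in seq_len(N)) {
      X <- matrix(0, C, n_time)
      for (i in seq_len(n_cmp)) {
        cmp <- spec$components[[i]]
        w <- switch(cmp$kind,
          trend = trend_waveform(n_time, spec$dt),
          task_block = block_regressor(cmp$block_onsets, cmp$block_duration,
                                       n_time, spec$dt),
          { # oscillatory kinds share the AM-FM tone model
            f <- cmp$center_freq_hz *
              (1 + runif(1, -cmp$jitter_freq, cmp$jitter_freq))
            truth$participant_freq[i, p] <- f
            tone_waveform(f, n_time, spec$dt, cmp$am_depth)
          })
        amp_fac <- 1 + runif(1, -cmp$jitter_amp, cmp$jitter_amp)
        l <- if (cmp$loading == "shared_modules") {
          base_load[[i]] * amp_fac
        } else {
          rnorm(C, sd = cmp$amplitude) * amp_fac
        }
        truth$loadings[[i]][p, ] <- l
        truth$waveforms[[i]][p, ] <- w
        X <- X + outer(l, w)
      }
      X <- X + matrix(rnorm(C * n_time, sd = spec$noise_sd), C, n_time)
      signals[[p]] <- mv_signal(X, dt = spec$dt, channel_labels = labels,
                                participant_id = sprintf("sub-%03d", p),
                                byrow = TRUE)
    }
  })
  list(signals = signals, truth = truth)
}

#' Module ordering of a synthetic spec
#'
#' @param spec A `synthetic_spec`.
#' @return A [module_ordering()] for the spec's ROI labels and modules.
#' @export
spec_module_ordering <- function(spec) {
  labels <- paste0("ROI", sprintf("%02d", seq_len(spec$n_rois)))
  mod <- character(spec$n_rois)
  for (m in names(spec$modules)) mod[spec$modules[[m]]] <- m
  module_ordering(labels, mod)
}
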