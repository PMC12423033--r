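# shared fixtures built in code

TR <- 0.72

tone_matrix <- function(freqs, n_channels, n = 1200, dt = TR, amps = NULL,
                        phases = NULL) {
  t <- (seq_len(n) - 1) * dt
  if (is.null(amps)) amps <- rep(1, length(freqs))
  if (is.null(phases)) phases <- rep(0, length(freqs))
  w <- rowSums(mapply(function(f, a, ph) a * cos(2 * pi * f * t + ph),
                      freqs, amps, phases))
  m <- matrix(rep(w, each = n_channels), n_channels, n, byrow = FALSE)
  m - rowMeans(m)
}

# cohort decompositions are expensive; cache them across test files
cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(seed, k = 6) {
  key <- paste0("s", seed, "k", k)
  if (is.null(cohort_cache[[key]])) {
    cohort <- generate_cohort(default_cohort_spec(seed = seed))
    ms <- lapply(cohort$signals, mvmd, k = k)
    cohort_cache[[key]] <- list(cohort = cohort, modesets = ms)
  }
  cohort_cache[[key]]
}

# cohort-level band selection (majority across participants), compared with
# the mode indices matched to the planted components
cohort_selection_ok <- function(cohort, ms) {
  n_part <- length(ms)
  inband <- rowMeans(sapply(ms, function(m) {
    classify_bands(m$omega_hz) == "neurophysiological"
  }))
  sel <- which(inband > 0.5)
  match_idx <- function(row) {
    sapply(seq_len(n_part), function(p) {
      which.min(abs(ms[[p]]$omega_hz - cohort$truth$participant_freq[row, p]))
    })
  }
  majority <- function(v) as.integer(names(which.max(table(v))))
  neural_rows <- which(cohort$truth$components$kind == "neural_oscillation")
  resp_rows <- which(cohort$truth$components$kind %in%
                       c("respiratory", "cardiac"))
  maj_neural <- sort(vapply(neural_rows, function(r) majority(match_idx(r)),
                            integer(1)))
  maj_resp <- vapply(resp_rows, function(r) majority(match_idx(r)), integer(1))
  setequal(sel, maj_neural) && !any(maj_resp %in% sel)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in all_permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
    }
  }
  out
}

# small decomposition reused across tests (noiseless two-tone, 3 channels)
fixture_decomp <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- tone_matrix(c(0.02, 0.10), 3)
      cache <<- mvmd(t(m), dt = TR, k = 2, tau = 2.5)
    }
    cache
  }
})
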