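#' Pipeline configuration
#'
#' Collects everything one reproducible run needs: where the data comes
#' from (delimited time-series files, or a [synthetic_spec()] to simulate),
#' the decomposition parameters, the band table, the connectivity test
#' settings, and the output directory. Validated up front so a run fails
#' before any heavy computation.
#'
#' @param input_paths Character vector of time-series files (one per
#'   participant), or `NULL` when `simulate` is given.
#' @param simulate A [synthetic_spec()] to generate the cohort instead of
#'   reading files.
#' @param dt Sampling interval in seconds (required for file input).
#' @param params [mvmd_params()] for the decomposition stage.
#' @param band_defs Band table; defaults to [band_definitions()] at the
#'   run's Nyquist frequency.
#' @param modules_path Optional ROI-to-module table for matrix ordering.
#' @param n_perm Null permutations per participant.
#' @param q FDR level of the edge tests.
#' @param n_stat_perm Label permutations of the edge t-tests.
#' @param fc_modes `"neurophysiological"` (default: the band-selected
#'   modes, pooled across participants by majority), `"all"`, or an
#'   integer vector of mode indices.
#' @param out_dir Output directory for [run_pipeline()].
#' @param seed Integer master seed for every stochastic stage.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(input_paths = NULL, simulate = NULL, dt = NULL,
                            params = mvmd_params(), band_defs = NULL,
                            modules_path = NULL, n_perm = 200, q = 0.001,
                            n_stat_perm = 10000,
                            fc_modes = "neurophysiological",
                            out_dir = "modefc_run", seed = 1) {
  if (is.null(input_paths) && is.null(simulate)) {
    stop_modefc("supply `input_paths` or a `simulate` spec")
  }
  if (!is.null(input_paths)) {
    missing <- input_paths[!file.exists(input_paths)]
    if (length(missing)) {
      stop_modefc("input file(s) not found: ", paste(missing, collapse = ", "))
    }
    if (is.null(dt)) stop_modefc("`dt` is required for file input")
  }
  if (!is.null(simulate)) {
    if (!inherits(simulate, "synthetic_spec")) {
      stop_modefc("`simulate` must be a synthetic_spec")
    }
    dt <- simulate$dt
  }
  if (!is.null(modules_path) && !file.exists(modules_path)) {
    stop_modefc("modules file not found: ", modules_path)
  }
  if (q <= 0 || q >= 1) stop_modefc("`q` must be in (0, 1)")
  structure(
    list(input_paths = input_paths, simulate = simulate, dt = dt,
         params = params, band_defs = band_defs,
         modules_path = modules_path, n_perm = as.integer(n_perm), q = q,
         n_stat_perm = as.integer(n_stat_perm), fc_modes = fc_modes,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

config_digest <- function(config) {
  # content hash of the run-defining settings (djb2 over the deparsed
  # config; stable across sessions, no extra dependencies)
  txt <- paste(deparse(unclass(config)[setdiff(names(config), "out_dir")]),
               collapse = "")
  h <- 5381
  for (v in utf8ToInt(txt)) h <- (h * 33 + v) %% 2^31
  sprintf("%08x", h)
}

write_matrix_tsv <- function(m, path) {
  df <- as.data.frame(m)
  if (is.null(names(df)) || all(grepl("^V[0-9]+$", names(df)))) {
    names(df) <- paste0("ROI", sprintf("%02d", seq_len(ncol(m))))
  }
  readr::write_tsv(tibble::as_tibble(df), path, progress = FALSE)
}

#' Run the full multiscale connectivity pipeline
#'
#' Executes the four stages — ingest (or simulate), decompose, band
#' selection, per-mode connectivity — plus reproducibility, writing all
#' results under `config$out_dir`:
#' \itemize{
#'   \item `modesets/<participant>/` — serialized decompositions
#'   \item `band_profile.tsv` — per participant and mode: central
#'     frequency, bandwidth, relative energy, band
#'   \item `band_summary.tsv` — per mode: mean central frequency, mean and
#'     sd of bandwidth across participants
#'   \item `fc_mode_<k>.tsv`, `fc_mode_<k>_significant.tsv` — group-mean
#'     Fisher-Z matrices and significance masks
#'   \item `reproducibility.tsv` — all-pairs similarity per mode
#'   \item `manifest.json` — config digest, seed, selected modes, package
#'     version, completion flag
#' }
#' Rerunning with the same configuration and seed reproduces every numeric
#' output bit-identically.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return The run directory path, invisibly; the manifest as attribute
#'   `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) {
    stop_modefc("`config` must come from pipeline_config()")
  }
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    config_digest = config_digest(config), seed = config$seed,
    package_version = as.character(utils::packageVersion("modefc")),
    q = config$q, n_perm = config$n_perm, n_stat_perm = config$n_stat_perm,
    complete = FALSE
  )
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  write_manifest()
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      write_manifest()
      stop_modefc("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  # Stage I: ingest or simulate
  signals <- stage("ingest", {
    if (!is.null(config$simulate)) {
      say("simulating cohort (seed ", config$simulate$seed, ")")
      generate_cohort(config$simulate)$signals
    } else {
      say("reading ", length(config$input_paths), " time-series file(s)")
      lapply(config$input_paths, read_timeseries, dt = config$dt)
    }
  })
  ordering <- if (!is.null(config$modules_path)) {
    stage("ingest", read_modules(config$modules_path,
                                 signals[[1]]$channel_labels))
  } else if (!is.null(config$simulate)) {
    spec_module_ordering(config$simulate)
  } else {
    NULL
  }

  # Stage II: decomposition
  modesets <- stage("decompose", {
    lapply(seq_along(signals), function(p) {
      say("decomposing participant ", p, "/", length(signals))
      ms <- mvmd(signals[[p]], params = config$params)
      write_modeset(ms, file.path(config$out_dir, "modesets",
                                  sprintf("participant_%03d", p)))
      ms
    })
  })

  # Stage III: band profiling and mode selection
  defs <- if (is.null(config$band_defs)) {
    band_definitions(nyquist_hz(config$dt))
  } else {
    validate_band_definitions(config$band_defs)
  }
  sel <- stage("profile", {
    profiles <- purrr::map_dfr(seq_along(modesets), function(p) {
      dplyr::mutate(band_profile(modesets[[p]], defs), participant = p,
                    .before = 1)
    })
    readr::write_tsv(profiles, file.path(config$out_dir, "band_profile.tsv"),
                     progress = FALSE)
    summary <- profiles |>
      dplyr::group_by(.data$mode) |>
      dplyr::summarise(
        mean_freq_hz = mean(.data$central_freq_hz),
        mean_bw_hz = mean(.data$bandwidth_hz),
        sd_bw_hz = sd(.data$bandwidth_hz),
        mean_rel_energy = mean(.data$rel_energy),
        band = names(which.max(table(.data$band)))
      )
    readr::write_tsv(summary, file.path(config$out_dir, "band_summary.tsv"),
                     progress = FALSE)
    if (identical(config$fc_modes, "neurophysiological")) {
      # majority vote across participants for each mode index
      votes <- profiles |>
        dplyr::group_by(.data$mode) |>
        dplyr::summarise(inband = mean(.data$band == "neurophysiological"))
      sel <- votes$mode[votes$inband > 0.5]
      if (!length(sel)) {
        warning("no mode is in the neurophysiological band for most participants",
                call. = FALSE)
      }
      sel
    } else if (identical(config$fc_modes, "all")) {
      seq_len(config$params$k)
    } else {
      as.integer(config$fc_modes)
    }
  })
  manifest$selected_modes <- sel
  write_manifest()

  # Stage IV: connectivity + reproducibility
  stage("fc", {
    repro <- list()
    for (k in sel) {
      say("connectivity for mode ", k)
      res <- fc_analysis(modesets, k, n_perm = config$n_perm, q = config$q,
                         n_stat_perm = config$n_stat_perm,
                         seed = config$seed + 1000L * k)
      gm <- res$group_mean_z
      mask <- res$significant
      if (!is.null(ordering)) {
        gm <- order_by_module(gm, ordering)
        mask <- order_by_module(mask, ordering)
      }
      write_matrix_tsv(gm, file.path(config$out_dir,
                                     sprintf("fc_mode_%02d.tsv", k)))
      write_matrix_tsv(mask, file.path(config$out_dir,
                                       sprintf("fc_mode_%02d_significant.tsv", k)))
      if (dim(res$per_participant_z)[1] >= 2) {
        repro[[as.character(k)]] <- glance(pairwise_similarity(res))
      }
    }
    if (length(repro)) {
      readr::write_tsv(dplyr::bind_rows(repro),
                       file.path(config$out_dir, "reproducibility.tsv"),
                       progress = FALSE)
    }
  })

  manifest$complete <- TRUE
  write_manifest()
  say("run complete: ", config$out_dir)
  out <- config$out_dir
  attr(out, "manifest") <- manifest
  invisible(out)
}
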