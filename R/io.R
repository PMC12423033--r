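#' Read a delimited ROI time-series file
#'
#' Expects comma- or tab-delimited text with a header row of ROI labels and
#' one row per time point. Columns become channels; each channel is
#' mean-centered on ingest. Ragged rows and non-numeric cells are rejected
#' with the offending location named.
#'
#' @param path File path.
#' @param dt Sampling interval in seconds.
#' @param header Set `FALSE` for files without a label row (labels are then
#'   generated as `ROI1, ROI2, ...`).
#' @param participant_id Optional identifier; defaults to the file name.
#' @return An [mv_signal].
#' @export
read_timeseries <- function(path, dt, header = TRUE, participant_id = NULL) {
  if (!file.exists(path)) stop_modefc("file not found: ", path)
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  raw <- tryCatch(
    readr::read_delim(path, delim = delim, col_names = header,
                      col_types = readr::cols(.default = readr::col_character()),
                      progress = FALSE),
    error = function(e) stop_modefc("cannot parse ", path, ": ", conditionMessage(e))
  )
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    stop_modefc("ragged or malformed row(s) in ", path, ": row ",
                paste(unique(prob$row), collapse = ", "),
                if (!header) " (is there a header? use header = TRUE)" else "")
  }
  if (header && any(!is.na(suppressWarnings(as.numeric(names(raw)))))) {
    stop_modefc("header row of ", path, " looks numeric; ",
                "pass header = FALSE for files without ROI labels")
  }
  num <- suppressWarnings(
    dplyr::mutate(raw, dplyr::across(dplyr::everything(), as.numeric))
  )
  bad <- which(as.matrix(is.na(num)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    loc <- utils::head(apply(bad, 1, function(b) {
      paste0("row ", b[1], " / column ", names(raw)[b[2]])
    }), 5)
    stop_modefc("non-numeric or missing cell(s) in ", path, ": ",
                paste(loc, collapse = "; "))
  }
  if (is.null(participant_id)) participant_id <- basename(path)
  mv_signal(num, dt = dt, participant_id = participant_id)
}

#' Write an ROI time series as delimited text
#'
#' Tab-separated, header row of ROI labels, one row per time point, full
#' float precision (round-trips through [read_timeseries()] exactly, up to
#' the mean-centering applied on ingest).
#'
#' @param sig An [mv_signal].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(sig, path) {
  if (!inherits(sig, "mv_signal")) stop_modefc("`sig` must be an mv_signal")
  df <- as.data.frame(t(sig$data))
  names(df) <- sig$channel_labels
  readr::write_tsv(tibble::as_tibble(df), path, progress = FALSE)
  invisible(path)
}

#' Read an ROI-to-module table
#'
#' Two-column delimited text (`roi_label`, `module_name`, with or without
#' a header). ROIs are grouped by module in file order of first appearance.
#'
#' @param path File path.
#' @param roi_labels Optional character vector to validate against (e.g.
#'   the time-series header); mismatches raise an error listing them.
#' @return A [module_ordering()].
#' @export
read_modules <- function(path, roi_labels = NULL) {
  if (!file.exists(path)) stop_modefc("file not found: ", path)
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, col_names = FALSE,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  if (ncol(tab) != 2) stop_modefc("expected two columns (roi_label, module_name)")
  if (identical(tolower(unlist(tab[1, ])), c("roi_label", "module_name"))) {
    tab <- tab[-1, ]
  }
  if (!is.null(roi_labels)) {
    missing_file <- setdiff(roi_labels, tab[[1]])
    extra_file <- setdiff(tab[[1]], roi_labels)
    if (length(missing_file) || length(extra_file)) {
      stop_modefc(
        "module table does not match the time-series labels",
        if (length(missing_file)) paste0("; absent from table: ",
                                         paste(missing_file, collapse = ", ")),
        if (length(extra_file)) paste0("; unknown in table: ",
                                       paste(extra_file, collapse = ", "))
      )
    }
  }
  module_ordering(tab[[1]], tab[[2]])
}

#' Serialize a decomposition to a directory
#'
#' Writes `omega.tsv` (mode index, central frequency in Hz),
#' `mode_<k>.tsv` (time x channels, labeled header) per mode, and
#' `meta.json` (parameters, dt, convergence diagnostics). Full float
#' precision; [read_modeset()] restores the object losslessly.
#'
#' @param ms An [mvmd_decomp].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_modeset <- function(ms, dir) {
  if (!inherits(ms, "mvmd_decomp")) stop_modefc("`ms` must be an mvmd_decomp")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  K <- dim(ms$modes)[1]
  readr::write_tsv(
    tibble::tibble(mode = seq_len(K), omega_hz = ms$omega_hz),
    file.path(dir, "omega.tsv"), progress = FALSE
  )
  for (k in seq_len(K)) {
    df <- as.data.frame(t(mode_matrix(ms, k)))
    names(df) <- ms$channel_labels
    readr::write_tsv(tibble::as_tibble(df),
                     file.path(dir, sprintf("mode_%02d.tsv", k)),
                     progress = FALSE)
  }
  resid <- as.data.frame(t(ms$residual))
  names(resid) <- ms$channel_labels
  readr::write_tsv(tibble::as_tibble(resid), file.path(dir, "residual.tsv"),
                   progress = FALSE)
  meta <- list(
    params = unclass(ms$params), dt = ms$dt,
    iterations = ms$iterations, converged = ms$converged,
    channel_labels = ms$channel_labels,
    participant_id = ms$participant_id
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' Restore a decomposition written by [write_modeset()]
#'
#' @param dir Directory containing `omega.tsv`, `mode_*.tsv`,
#'   `residual.tsv` and `meta.json`.
#' @return An [mvmd_decomp].
#' @export
read_modeset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  omega <- readr::read_tsv(file.path(dir, "omega.tsv"),
                           col_types = "id", progress = FALSE)
  K <- nrow(omega)
  read_mat <- function(f) {
    t(as.matrix(readr::read_tsv(f, col_types = readr::cols(.default = "d"),
                                progress = FALSE)))
  }
  resid <- read_mat(file.path(dir, "residual.tsv"))
  modes <- array(NA_real_, c(K, nrow(resid), ncol(resid)))
  for (k in seq_len(K)) {
    modes[k, , ] <- read_mat(file.path(dir, sprintf("mode_%02d.tsv", k)))
  }
  dimnames(modes) <- list(NULL, meta$channel_labels, NULL)
  params <- do.call(mvmd_params, meta$params[
    setdiff(names(meta$params), character(0))
  ])
  structure(
    list(modes = modes, omega_hz = omega$omega_hz, residual = resid,
         iterations = meta$iterations, converged = meta$converged,
         params = params, dt = meta$dt,
         channel_labels = meta$channel_labels,
         participant_id = meta$participant_id),
    class = "mvmd_decomp"
  )
}
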