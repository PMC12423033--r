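#' Vectorize the upper triangle of a symmetric matrix
#'
#' Returns the strictly-upper-triangular entries in row-major order:
#' `(1,2), (1,3), ..., (1,C), (2,3), ..., (C-1,C)` — the fixed edge order
#' used when correlating connectivity matrices. Length is `C(C-1)/2`.
#'
#' @param m Square matrix.
#' @return Numeric vector of length `C(C-1)/2`.
#' @examples
#' vectorize_upper(matrix(1:9, 3, byrow = TRUE)) # 2 3 6
#' @export
vectorize_upper <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop_modefc("`m` must be square")
  t(m)[lower.tri(m)]
}

#' Cross-participant reproducibility of connectivity patterns
#'
#' Pearson correlation between the vectorized upper triangles of every
#' unordered pair of participants' connectivity matrices — the all-pairs
#' similarity used to ask whether a mode's connectivity is a stable trait
#' of the cohort or an individual idiosyncrasy. A participant whose
#' connectivity vector is constant yields `NA` for its pairs (excluded
#' from summaries, with a warning).
#'
#' @param fc_stack Array `N x C x C` of per-participant connectivity
#'   matrices (Fisher-Z recommended, matching how group matrices are
#'   averaged and tested), or an [fc_result] object.
#' @param mode_index Mode index recorded in the result (taken from an
#'   `fc_result` automatically).
#' @return An object of class `fc_reproducibility`: `pair_similarities`
#'   (length `N(N-1)/2`), `pairs` (participant index pairs), `mode_index`,
#'   and `summary` (median, quartiles, mean). [tidy()] returns one row per
#'   pair, [glance()] the summary row.
#' @examples
#' z <- array(rnorm(5 * 6 * 6), c(5, 6, 6))
#' for (i in 1:5) z[i, , ] <- z[i, , ] + t(z[i, , ])
#' rep_res <- pairwise_similarity(z)
#' glance(rep_res)
#' @export
pairwise_similarity <- function(fc_stack, mode_index = NA_integer_) {
  if (inherits(fc_stack, "fc_result")) {
    mode_index <- fc_stack$mode_index
    fc_stack <- fc_stack$per_participant_z
  }
  if (!is.array(fc_stack) || length(dim(fc_stack)) != 3) {
    stop_modefc("`fc_stack` must be an N x C x C array")
  }
  N <- dim(fc_stack)[1]
  if (N < 2) stop_modefc("need at least 2 participants")
  vecs <- vapply(seq_len(N), function(i) vectorize_upper(fc_stack[i, , ]),
                 numeric(dim(fc_stack)[2] * (dim(fc_stack)[2] - 1) / 2))
  vecs <- matrix(vecs, ncol = N)
  const <- apply(vecs, 2, function(v) sd(v) == 0 || anyNA(v))
  if (any(const)) {
    warning("participant(s) ", paste(which(const), collapse = ", "),
            " have constant connectivity vectors; their pairs are NA",
            call. = FALSE)
  }
  pairs <- which(upper.tri(diag(N)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  sims <- vapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (const[i] || const[j]) return(NA_real_)
    cor(vecs[, i], vecs[, j])
  }, numeric(1))
  ok <- sims[!is.na(sims)]
  structure(
    list(
      mode_index = mode_index,
      pair_similarities = sims,
      pairs = tibble::tibble(participant_i = pairs[, 1],
                             participant_j = pairs[, 2]),
      summary = c(median = median(ok), q1 = unname(quantile(ok, 0.25)),
                  q3 = unname(quantile(ok, 0.75)), mean = mean(ok))
    ),
    class = "fc_reproducibility"
  )
}

#' @export
print.fc_reproducibility <- function(x, ...) {
  cat("<fc_reproducibility>", length(x$pair_similarities), "participant pairs")
  if (!is.na(x$mode_index)) cat(" (mode ", x$mode_index, ")", sep = "")
  cat("\nmedian similarity ", format(x$summary[["median"]], digits = 3),
      "  IQR [", format(x$summary[["q1"]], digits = 3), ", ",
      format(x$summary[["q3"]], digits = 3), "]\n", sep = "")
  invisible(x)
}

#' @rdname pairwise_similarity
#' @param x An `fc_reproducibility` object.
#' @param ... Unused.
#' @method tidy fc_reproducibility
#' @export
tidy.fc_reproducibility <- function(x, ...) {
  dplyr::mutate(x$pairs,
                mode = x$mode_index,
                similarity = x$pair_similarities,
                .before = 1)
}

#' @rdname pairwise_similarity
#' @method glance fc_reproducibility
#' @export
glance.fc_reproducibility <- function(x, ...) {
  tibble::tibble(
    mode = x$mode_index,
    n_pairs = length(x$pair_similarities),
    median = x$summary[["median"]],
    q1 = x$summary[["q1"]],
    q3 = x$summary[["q3"]],
    mean = x$summary[["mean"]]
  )
}
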