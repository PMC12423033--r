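#' Pearson functional-connectivity matrix of a mode
#'
#' Correlation between every pair of channels of one mode's waveforms.
#' Constant channels cannot be correlated; their rows and columns are set
#' to 0 (diagonal kept at 1) with a warning.
#'
#' @param mode Numeric matrix, channels x time.
#' @return Symmetric C x C correlation matrix with unit diagonal.
#' @export
fc_matrix <- function(mode) {
  if (!is.matrix(mode) || !is.numeric(mode)) {
    stop_modefc("`mode` must be a numeric matrix (channels x time)")
  }
  if (nrow(mode) < 2) stop_modefc("need at least 2 channels")
  if (ncol(mode) < 3) stop_modefc("need at least 3 time points")
  sds <- apply(mode, 1, sd)
  const <- sds == 0
  r <- suppressWarnings(cor(t(mode)))
  if (any(const)) {
    warning(sum(const), " constant channel(s); their correlations set to 0",
            call. = FALSE)
    r[const, ] <- 0
    r[, const] <- 0
  }
  diag(r) <- 1
  r[r > 1] <- 1
  r[r < -1] <- -1
  r
}

#' Fisher-Z transform of correlation values
#'
#' `atanh(r)` elementwise, the variance-stabilizing transform applied to
#' correlations before averaging and testing. Values with `|r| = 1` are
#' clipped to `1 - 1e-7` so the transform stays finite.
#'
#' @param r Correlation value, vector or matrix with entries in `[-1, 1]`.
#' @return Same shape as `r`.
#' @examples
#' fisher_z(0.5) # 0.5493
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    stop_modefc("correlations must lie in [-1, 1]")
  }
  clip <- 1 - 1e-7
  atanh(pmin(pmax(r, -clip), clip))
}

#' Permutation null for one mode's connectivity
#'
#' Builds the null distribution of Fisher-Z connectivity under "no
#' cross-channel dependence" by randomly mixing the temporal samples of the
#' mode: each draw permutes the time indices *independently per channel*
#' (a shared permutation would preserve cross-channel alignment and yield
#' a degenerate null) and recomputes the Fisher-Z correlation matrix. The
#' null series keep each channel's amplitude distribution while destroying
#' temporal and cross-channel structure.
#'
#' @param ms An [mvmd_decomp] object, or a channels x time matrix.
#' @param mode_index Which mode to shuffle (ignored for matrix input).
#' @param n_perm Number of permutations; fewer than 100 triggers a warning.
#' @param seed Integer seed; same seed, same null.
#' @return Array `n_perm x C x C` of Fisher-Z matrices.
#' @export
build_null <- function(ms, mode_index = 1, n_perm = 200, seed = NULL) {
  m <- if (inherits(ms, "mvmd_decomp")) mode_matrix(ms, mode_index) else ms
  if (!is.matrix(m)) stop_modefc("`ms` must be an mvmd_decomp or a matrix")
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1) stop_modefc("`n_perm` must be a positive integer")
  if (n_perm < 100) {
    warning("n_perm = ", n_perm, " is small; 100+ recommended", call. = FALSE)
  }
  C <- nrow(m)
  n_time <- ncol(m)
  out <- array(NA_real_, c(n_perm, C, C))
  with_local_seed(seed, {
    for (p in seq_len(n_perm)) {
      shuf <- m
      for (cc in seq_len(C)) shuf[cc, ] <- m[cc, sample.int(n_time)]
      out[p, , ] <- fisher_z(fc_matrix(shuf))
    }
  })
  out
}

#' Elementwise mean of Fisher-Z connectivity matrices
#'
#' @param z_stack Array `N x C x C` of per-participant Fisher-Z matrices
#'   (or a single C x C matrix, returned as is).
#' @return C x C matrix of means.
#' @export
average_fc <- function(z_stack) {
  if (is.matrix(z_stack)) return(z_stack)
  if (!is.array(z_stack) || length(dim(z_stack)) != 3) {
    stop_modefc("`z_stack` must be an N x C x C array")
  }
  colMeans(z_stack)
}

upper_edges <- function(C) which(upper.tri(matrix(0, C, C)))

#' Edge-level significance by permutation t-test with FDR control
#'
#' For every off-diagonal edge, contrasts the `N` observed Fisher-Z values
#' with the pooled null values (from [build_null()]) by a two-sample Welch
#' t statistic. Its two-sided p-value is the fraction of label-shuffled
#' statistics at least as extreme, with tail continuity correction
#' `p = (b + 1) / (n_stat_perm + 1)`; label permutations are shared across
#' edges within one call. Benjamini-Hochberg step-up at level `q` over the
#' upper-triangle edges yields the significance mask.
#'
#' Note the resolution limit of permutation p-values: the smallest
#' attainable p is `1 / (n_stat_perm + 1)`, so BH at level `q` over `E`
#' edges can only ever flag edges when `q / E >= 1 / (n_stat_perm + 1)`.
#'
#' Edges touching a channel whose observed values are all `NA` (constant
#' channels excluded upstream) are reported as `NA` in the mask.
#'
#' @param observed_z Array `N x C x C` of per-participant Fisher-Z matrices.
#' @param nulls Array `N x n_perm x C x C` (per-participant nulls), or
#'   `n_perm x C x C` to share one null set across participants.
#' @param q FDR level, default 0.001.
#' @param n_stat_perm Number of label permutations for the t statistic.
#' @param seed Integer seed for the label shuffles.
#' @return Symmetric logical C x C matrix (diagonal `FALSE`), with
#'   attributes `p_value` and `t_stat` (C x C matrices).
#' @export
group_significance <- function(observed_z, nulls, q = 0.001,
                               n_stat_perm = 10000, seed = NULL) {
  if (!is.array(observed_z) || length(dim(observed_z)) != 3) {
    stop_modefc("`observed_z` must be an N x C x C array")
  }
  N <- dim(observed_z)[1]
  C <- dim(observed_z)[2]
  if (N < 2) stop_modefc("need at least 2 participants")
  if (!is.numeric(q) || q <= 0 || q >= 1) stop_modefc("`q` must be in (0, 1)")
  if (length(dim(nulls)) == 3) {
    # one shared null set: replicate across participants
    shared <- nulls
    nulls <- array(NA_real_, c(N, dim(shared)))
    for (p in seq_len(N)) nulls[p, , , ] <- shared
  }
  if (length(dim(nulls)) != 4 || dim(nulls)[1] != N || any(dim(nulls)[3:4] != C)) {
    stop_modefc("`nulls` must be N x n_perm x C x C matching `observed_z`")
  }
  edges <- upper_edges(C)
  E <- length(edges)
  # observed values per edge: N x E
  obs <- matrix(observed_z, nrow = N)[, edges, drop = FALSE]
  # pooled null values per edge: (N * n_perm) x E
  nul <- matrix(aperm(nulls, c(2, 1, 3, 4)), nrow = N * dim(nulls)[2])[, edges, drop = FALSE]
  usable <- colSums(is.na(obs)) == 0 & colSums(is.na(nul)) == 0

  welch_t <- function(m1, v1, n1, m2, v2, n2) {
    (m1 - m2) / sqrt(v1 / n1 + v2 / n2)
  }
  n2 <- nrow(nul)
  t_obs <- rep(NA_real_, E)
  p_val <- rep(NA_real_, E)
  if (any(usable)) {
    m1 <- colMeans(obs[, usable, drop = FALSE])
    v1 <- apply(obs[, usable, drop = FALSE], 2, var)
    m2 <- colMeans(nul[, usable, drop = FALSE])
    v2 <- apply(nul[, usable, drop = FALSE], 2, var)
    t_obs[usable] <- welch_t(m1, v1, N, m2, v2, n2)

    V <- rbind(obs[, usable, drop = FALSE], nul[, usable, drop = FALSE])
    M <- nrow(V)
    tot_s <- colSums(V)
    tot_ss <- colSums(V^2)
    exceed <- numeric(sum(usable))
    with_local_seed(seed, {
      for (b in seq_len(n_stat_perm)) {
        idx <- sample.int(M, N)
        g1 <- V[idx, , drop = FALSE]
        s1 <- colSums(g1)
        ss1 <- colSums(g1^2)
        mm1 <- s1 / N
        vv1 <- (ss1 - N * mm1^2) / (N - 1)
        s2 <- tot_s - s1
        ss2 <- tot_ss - ss1
        mm2 <- s2 / (M - N)
        vv2 <- (ss2 - (M - N) * mm2^2) / (M - N - 1)
        tb <- welch_t(mm1, vv1, N, mm2, vv2, M - N)
        exceed <- exceed + (abs(tb) >= abs(t_obs[usable]) - 1e-12)
      }
    })
    p_val[usable] <- (exceed + 1) / (n_stat_perm + 1)
  }
  p_adj <- rep(NA_real_, E)
  p_adj[usable] <- p.adjust(p_val[usable], method = "BH")
  sig_edges <- p_adj <= q

  to_mat <- function(v, diag_val) {
    m <- matrix(diag_val, C, C)
    m[edges] <- v
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  mask <- to_mat(sig_edges, FALSE)
  attr(mask, "p_value") <- to_mat(p_val, NA_real_)
  attr(mask, "t_stat") <- to_mat(t_obs, NA_real_)
  mask
}

#' Reorder a connectivity matrix by functional module
#'
#' Applies one simultaneous row/column permutation so that ROIs of the same
#' module are contiguous — the standard presentation of parcellated FC
#' matrices. Applying the inverse ordering recovers the original matrix.
#'
#' @param m Square matrix with row/column names matching `ordering`'s
#'   labels (unnamed matrices are indexed positionally).
#' @param ordering A `module_ordering` object from [module_ordering()] or
#'   [read_modules()].
#' @return The reordered matrix, with a `module` attribute giving each
#'   row's module.
#' @export
order_by_module <- function(m, ordering) {
  if (!inherits(ordering, "module_ordering")) {
    stop_modefc("`ordering` must be a module_ordering")
  }
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop_modefc("`m` must be square")
  idx <- ordering$ordered_indices
  if (!is.null(rownames(m))) {
    missing <- setdiff(rownames(m), ordering$roi_labels)
    if (length(missing)) {
      stop_modefc("labels absent from the ordering: ",
                  paste(missing, collapse = ", "))
    }
    idx <- match(ordering$roi_labels[idx], rownames(m))
  } else if (nrow(m) != length(idx)) {
    stop_modefc("matrix size ", nrow(m), " does not match ordering size ",
                length(idx))
  }
  out <- m[idx, idx, drop = FALSE]
  attr(out, "module") <- ordering$module_of[ordering$ordered_indices]
  out
}

#' Construct a module ordering for a parcellation
#'
#' @param roi_labels Character vector of ROI labels.
#' @param module_of Character vector (same length) of module names, or a
#'   named vector mapping label to module.
#' @return A `module_ordering` object: labels, module map, and the
#'   permutation making modules contiguous (file order of first
#'   appearance).
#' @export
module_ordering <- function(roi_labels, module_of) {
  roi_labels <- as.character(roi_labels)
  if (anyDuplicated(roi_labels)) {
    stop_modefc("duplicate ROI label(s): ",
                paste(unique(roi_labels[duplicated(roi_labels)]), collapse = ", "))
  }
  if (!is.null(names(module_of))) module_of <- module_of[roi_labels]
  module_of <- as.character(module_of)
  if (length(module_of) != length(roi_labels) || anyNA(module_of)) {
    stop_modefc("`module_of` must give one module per ROI label")
  }
  lev <- unique(module_of)
  idx <- order(match(module_of, lev))
  structure(
    list(roi_labels = roi_labels,
         module_of = setNames(module_of, roi_labels),
         ordered_indices = idx),
    class = "module_ordering"
  )
}

#' @export
print.module_ordering <- function(x, ...) {
  tab <- table(factor(x$module_of, levels = unique(x$module_of[x$ordered_indices])))
  cat("<module_ordering>", length(x$roi_labels), "ROIs in", length(tab),
      "modules:\n")
  print(tab)
  invisible(x)
}

#' Per-mode group connectivity with significance
#'
#' Runs the full connectivity stage for one cohort: per participant,
#' Fisher-Z Pearson connectivity of the selected mode; a shuffled-mode
#' permutation null per participant; a group significance mask from the
#' permutation t-test under FDR control; and the group-average matrix.
#'
#' @param modesets List of [mvmd_decomp] objects (one per participant),
#'   all with the same number of channels and modes. Modes are matched
#'   across participants by index after the ascending-frequency sort.
#' @param mode_index Which mode's connectivity to estimate.
#' @param n_perm Null permutations per participant.
#' @param q FDR level for the significance mask.
#' @param n_stat_perm Label permutations for the edge t-tests.
#' @param seed Integer seed; per-participant null seeds are derived from it.
#' @return An object of class `fc_result`: `mode_index`,
#'   `per_participant_z` (N x C x C), `group_mean_z`, `significant`,
#'   `q_threshold`, `n_permutations`, `channel_labels`. [tidy()] returns
#'   one row per edge.
#' @export
fc_analysis <- function(modesets, mode_index, n_perm = 200, q = 0.001,
                        n_stat_perm = 10000, seed = 1) {
  if (inherits(modesets, "mvmd_decomp")) modesets <- list(modesets)
  if (!length(modesets) || !all(vapply(modesets, inherits, TRUE, "mvmd_decomp"))) {
    stop_modefc("`modesets` must be a list of mvmd_decomp objects")
  }
  C <- dim(modesets[[1]]$modes)[2]
  N <- length(modesets)
  labels <- modesets[[1]]$channel_labels
  obs <- array(NA_real_, c(N, C, C))
  nulls <- array(NA_real_, c(N, n_perm, C, C))
  for (p in seq_len(N)) {
    m <- mode_matrix(modesets[[p]], mode_index)
    obs[p, , ] <- fisher_z(fc_matrix(m))
    nulls[p, , , ] <- build_null(m, n_perm = n_perm, seed = seed + p)
  }
  mask <- if (N >= 2) {
    group_significance(obs, nulls, q = q, n_stat_perm = n_stat_perm,
                       seed = seed)
  } else {
    matrix(NA, C, C)
  }
  gm <- average_fc(obs)
  diag(gm) <- 0 # diagonal excluded from averaging/testing by convention
  dimnames(gm) <- list(labels, labels)
  structure(
    list(mode_index = mode_index, per_participant_z = obs,
         group_mean_z = gm, significant = mask, q_threshold = q,
         n_permutations = n_perm, channel_labels = labels),
    class = "fc_result"
  )
}

#' @export
print.fc_result <- function(x, ...) {
  C <- ncol(x$group_mean_z)
  nsig <- sum(x$significant[upper.tri(x$significant)], na.rm = TRUE)
  cat("<fc_result> mode ", x$mode_index, ": ", C, " x ", C,
      " group connectivity over ", dim(x$per_participant_z)[1],
      " participant(s)\n", sep = "")
  cat(nsig, "of", C * (C - 1) / 2, "edges significant at FDR q =",
      x$q_threshold, "\n")
  invisible(x)
}

#' @rdname fc_analysis
#' @param x An `fc_result` (for `tidy`/`glance`).
#' @param ... Unused.
#' @method tidy fc_result
#' @export
tidy.fc_result <- function(x, ...) {
  C <- ncol(x$group_mean_z)
  labs <- x$channel_labels
  ij <- which(upper.tri(x$group_mean_z), arr.ind = TRUE)
  tibble::tibble(
    mode = x$mode_index,
    roi_i = labs[ij[, 1]],
    roi_j = labs[ij[, 2]],
    mean_z = x$group_mean_z[ij],
    significant = x$significant[ij]
  )
}

#' @rdname fc_analysis
#' @method glance fc_result
#' @export
glance.fc_result <- function(x, ...) {
  ut <- upper.tri(x$group_mean_z)
  tibble::tibble(
    mode = x$mode_index,
    n_participants = dim(x$per_participant_z)[1],
    n_edges = sum(ut),
    n_significant = sum(x$significant[ut], na.rm = TRUE),
    mean_abs_z = mean(abs(x$group_mean_z[ut])),
    q_threshold = x$q_threshold
  )
}
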