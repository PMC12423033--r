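#' Plot the mode waveforms of a decomposition
#'
#' Small-multiple view of each mode's waveform for a few channels, labeled
#' by central frequency — the visual check that the decomposition separated
#' drift, band-limited oscillations and high-frequency physiology.
#'
#' @param object An [mvmd_decomp].
#' @param channels Channel labels or indices to draw (default: up to 3).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mvmd_decomp
#' @export
autoplot.mvmd_decomp <- function(object, channels = NULL, ...) {
  K <- dim(object$modes)[1]
  C <- dim(object$modes)[2]
  if (is.null(channels)) channels <- seq_len(min(3, C))
  if (is.character(channels)) channels <- match(channels, object$channel_labels)
  tt <- (seq_len(dim(object$modes)[3]) - 1) * object$dt
  df <- purrr::map_dfr(seq_len(K), function(k) {
    purrr::map_dfr(channels, function(cc) {
      tibble::tibble(
        mode = sprintf("mode %d (%.0f mHz)", k, 1000 * object$omega_hz[k]),
        roi = object$channel_labels[cc],
        time = tt,
        value = object$modes[k, cc, ]
      )
    })
  })
  df$mode <- factor(df$mode, levels = unique(df$mode))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   color = .data$roi)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~mode, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "amplitude", color = "ROI") +
    ggplot2::theme_minimal()
}

#' Connectivity heatmap with the lower/upper-triangle convention
#'
#' Lower triangle: the full group-mean Fisher-Z matrix. Upper triangle:
#' only the entries surviving the FDR-controlled permutation test (others
#' blank) — so one panel shows both the average pattern and what is
#' statistically defensible.
#'
#' @param object An [fc_result].
#' @param ordering Optional [module_ordering()] applied to rows/columns.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fc_result
#' @export
autoplot.fc_result <- function(object, ordering = NULL, ...) {
  gm <- object$group_mean_z
  mask <- object$significant
  if (!is.null(ordering)) {
    gm <- order_by_module(gm, ordering)
    mask <- order_by_module(mask, ordering)
  }
  C <- ncol(gm)
  labs <- rownames(gm)
  if (is.null(labs)) labs <- object$channel_labels
  disp <- gm
  disp[upper.tri(disp)] <- ifelse(mask[upper.tri(mask)] %in% TRUE,
                                  gm[upper.tri(gm)], NA_real_)
  diag(disp) <- NA_real_
  df <- tibble::tibble(
    roi_i = factor(rep(labs, C), levels = labs),
    roi_j = factor(rep(labs, each = C), levels = rev(labs)),
    z = as.vector(disp)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$roi_i, y = .data$roi_j,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", na.value = "grey92") +
    ggplot2::labs(
      title = sprintf("mode %d connectivity", object$mode_index),
      subtitle = sprintf(
        "lower: group mean Fisher-Z; upper: significant at FDR q = %g",
        object$q_threshold
      ),
      x = NULL, y = NULL, fill = "Fisher-Z"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}

#' Reproducibility boxplot across modes
#'
#' Boxplots of all-pairs cross-participant similarity, one box per mode —
#' modes whose connectivity is a shared trait stand out with high boxes.
#'
#' @param results List of [fc_reproducibility] objects (or a single one).
#' @return A ggplot object.
#' @export
plot_reproducibility <- function(results) {
  if (inherits(results, "fc_reproducibility")) results <- list(results)
  df <- purrr::map_dfr(results, tidy)
  df$mode <- factor(df$mode)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mode, y = .data$similarity)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.6,
                          outlier.size = 0.5) +
    ggplot2::labs(x = "intrinsic mode", y = "pairwise FC similarity (r)") +
    ggplot2::theme_minimal()
}
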