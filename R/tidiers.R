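# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' Tidy a randomized overlap test
#'
#' @param x An `overlap_permutation` from [randomized_overlap_test()].
#' @param ... Unused.
#' @return A tibble of the null statistic values, one row per iteration.
#' @export
#' @method tidy overlap_permutation
tidy.overlap_permutation <- function(x, ...) {
  tibble(iteration = seq_along(x$null_values), null_overlap = x$null_values)
}

#' @describeIn tidy.overlap_permutation One-row summary: observed statistic,
#'   null mean/sd, z-score and empirical p-value.
#' @export
#' @method glance overlap_permutation
glance.overlap_permutation <- function(x, ...) {
  mu <- mean(x$null_values)
  s <- sd(x$null_values)
  tibble(
    observed = x$observed,
    null_mean = mu,
    null_sd = s,
    z = if (isTRUE(s > 0)) (x$observed - mu) / s else NA_real_,
    p_value = x$p_value,
    n_iter = x$n_iter
  )
}

#' One-row summary of a fingerprint curve
#'
#' Reports the area under the curve (0.5 for a uniform library, smaller
#' for enriched ones) and the fraction of signal in the top 1% of bins.
#'
#' @param x A `fingerprint_curve` from [fingerprint()].
#' @param ... Unused.
#' @export
#' @method glance fingerprint_curve
glance.fingerprint_curve <- function(x, ...) {
  n <- nrow(x) - 1
  auc <- sum(diff(x$frac_bins) * (head(x$frac_signal, -1) + x$frac_signal[-1]) / 2)
  top1 <- 1 - x$frac_signal[max(1, which(x$frac_bins >= 0.99)[1] - 1)]
  tibble(auc = auc, frac_signal_top1pct_bins = top1, n_bins = n)
}

#' @export
#' @method autoplot fingerprint_curve
autoplot.fingerprint_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frac_bins, y = .data$frac_signal)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(...) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "Fraction of bins (ranked by coverage)",
      y = "Cumulative fraction of signal",
      title = "Fingerprint"
    )
}

#' @export
#' @method autoplot binned_track
autoplot.binned_track <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$start, y = .data$value)) +
    ggplot2::geom_step(...) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(
      x = "Position (bp)",
      y = sprintf("Coverage (%s)", track_norm(object)),
      title = sprintf("Binned track (%d bp bins)", track_bin_size(object))
    )
}

#' @export
#' @method autoplot overlap_permutation
autoplot.overlap_permutation <- function(object, bins = 30, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$null_overlap)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(
      x = "Null overlap statistic",
      y = "Iterations",
      title = sprintf("Observed = %d, p = %.3g", object$observed, object$p_value)
    )
}

#' @export
#' @method autoplot state_annotation
autoplot.state_annotation <- function(object, ...) {
  df <- object[!is.na(object$fraction), , drop = FALSE]
  df$state <- factor(df$state, levels = df$state[order(-df$fraction)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$state, y = .data$fraction)) +
    ggplot2::geom_col(...) +
    ggplot2::labs(x = NULL, y = "Fraction of assigned peaks") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
#' @method autoplot profile_matrix
autoplot.profile_matrix <- function(object, ...) {
  df <- tibble(
    bin = seq_len(ncol(object)),
    mean_signal = colMeans(object, na.rm = TRUE)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$mean_signal)) +
    ggplot2::geom_line(...) +
    ggplot2::labs(x = "Window bin (5' to 3')", y = "Mean signal", title = "Average profile")
}
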