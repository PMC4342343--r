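# ggplot2 helpers for the main result types.

#' Plot a length histogram
#'
#' @param histogram Tibble from [length_histogram()].
#' @return A ggplot object (bars per bin, filled by class when present).
#' @export
plot_length_histogram <- function(histogram) {
  p <- ggplot2::ggplot(histogram,
                       ggplot2::aes(x = .data$bin_lo, y = .data$count))
  p <- if ("class" %in% names(histogram)) {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data$class))
  } else {
    p + ggplot2::geom_col(fill = "grey20")
  }
  p + ggplot2::labs(x = "length (bin lower edge)", y = "sequences") +
    ggplot2::theme_minimal()
}

#' Plot an E-value bin summary
#'
#' @param bins Tibble from [evalue_bin_summary()].
#' @return A ggplot object.
#' @export
plot_evalue_bins <- function(bins) {
  bins$range <- factor(bins$range, levels = bins$range)
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$range, y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "E-value range", y = "% of hits") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a Kyte-Doolittle hydropathy profile
#'
#' @param profile Tibble from [kyte_doolittle_profile()].
#' @param threshold Horizontal reference line (default 1.6, the
#'   membrane-helix calling threshold).
#' @return A ggplot object.
#' @export
plot_hydropathy <- function(profile, threshold = 1.6) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$center, y = .data$hydropathy)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "residue (window center)",
                  y = "mean hydropathy (window 17)") +
    ggplot2::theme_minimal()
}

#' @describeIn em_allocate Plot the log-likelihood trace of an EM fit.
#' @param object An `em_fit` object.
#' @param ... Unused.
#' @export
autoplot.em_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$log_likelihood),
                       log_likelihood = object$log_likelihood)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration,
                                   y = .data$log_likelihood)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "EM iteration", y = "log-likelihood") +
    ggplot2::theme_minimal()
}
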