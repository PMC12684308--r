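# ggplot2 displays for the main result types.

#' Plot a line survival curve
#'
#' @param object A `survival_curve_df` from [survival_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.survival_curve_df <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$generation, y = .data$surviving_pct,
                               colour = .data$treatment)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::labs(x = "Generation", y = "Surviving lines (%)",
                  colour = "Treatment") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Plot standardized load profiles
#'
#' Line means with standard-error bars per annotation category, the
#' reference line pinned at one.
#'
#' @param standardized Output of [standardize_load()].
#' @return A ggplot.
#' @export
plot_load_profile <- function(standardized) {
  smry <- load_summary(standardized)
  smry$category <- factor(smry$category, levels = load_categories)
  ggplot2::ggplot(smry,
                  ggplot2::aes(x = .data$category, y = .data$mean,
                               colour = .data$line, group = .data$line)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      width = 0.2, position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = NULL, y = "Standardized derived count",
                  colour = "Line") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Histogram of ROH lengths per line
#'
#' @param segments ROH tibble from [call_roh()], optionally with a `line`
#'   column joined on.
#' @param bin_width_bp Bin width.
#' @return A ggplot.
#' @export
plot_roh_lengths <- function(segments, bin_width_bp = 250000) {
  ggplot2::ggplot(segments,
                  ggplot2::aes(x = .data$length_bp / 1000)) +
    ggplot2::geom_histogram(binwidth = bin_width_bp / 1000,
                            boundary = 0, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "ROH length (kb)", y = "Count") +
    ggplot2::theme_minimal()
}

#' Distribution of productivity records by scheme
#'
#' @param records Productivity tibble (see [assay_pairs()]).
#' @return A ggplot.
#' @export
plot_productivity <- function(records) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$pupae_count, fill = .data$scheme)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 30) +
    ggplot2::labs(x = "Pupae per vial", y = "Vials", fill = "Scheme") +
    ggplot2::theme_minimal()
}
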