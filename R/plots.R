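#' Plot a Welch PSD estimate
#'
#' One line per channel, PSD (microvolts^2/Hz) against frequency; vertical
#' guides can mark the candidate stimulation frequencies.
#'
#' @param object An `eeg_psd` from [welch_psd()].
#' @param mark Frequencies to mark with dashed guides (default 15 and 18 Hz).
#' @param xlim Frequency range to show, Hz.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.eeg_psd <- function(object, mark = c(15, 18), xlim = c(0, 50), ...) {
  df <- tibble::tibble(
    channel = rep(object$channel_names, each = length(object$freqs)),
    freq = rep(object$freqs, times = nrow(object$psd)),
    psd = as.vector(t(object$psd)))
  df <- df[df$freq >= xlim[1] & df$freq <= xlim[2], ]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$freq, .data$psd,
                                        color = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)",
                  y = expression(PSD ~ (mu * V^2 / Hz)),
                  color = "Channel") +
    ggplot2::theme_minimal()
  if (length(mark)) {
    p <- p + ggplot2::geom_vline(xintercept = mark, linetype = "dashed",
                                 alpha = 0.4)
  }
  p
}

#' Bar chart of cross-validated accuracy by classifier and feature set
#'
#' The usual layout for SSVEP classification results: one bar per
#' (classifier, feature set) with an error bar of one standard deviation
#' across folds and a guide at the 75% benchmark.
#'
#' @param results A tibble from [classify_all()].
#' @param benchmark Horizontal guide position, % (default 75; `NULL` to
#'   omit).
#' @return A ggplot object.
#' @export
plot_cv_accuracy <- function(results, benchmark = 75) {
  p <- ggplot2::ggplot(results,
                       ggplot2::aes(toupper(.data$classifier),
                                    .data$mean_accuracy,
                                    fill = .data$feature_set)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_accuracy - .data$sd_accuracy,
                   ymax = .data$mean_accuracy + .data$sd_accuracy),
      position = ggplot2::position_dodge(0.8), width = 0.2) +
    ggplot2::labs(x = NULL, y = "Mean CV accuracy (%)",
                  fill = "Feature set") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
  if (!is.null(benchmark)) {
    p <- p + ggplot2::geom_hline(yintercept = benchmark,
                                 linetype = "dashed", alpha = 0.5)
  }
  p
}
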