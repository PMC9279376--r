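#' Plot activity counts per epoch
#'
#' @param object An `activity_counts` tibble from [activity_counts()].
#' @param ... Unused.
#' @return A ggplot: counts per epoch, one panel per axis.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.activity_counts <- function(object, ...) {
  long <- tidy.activity_counts(object)
  epoch_len <- attr(object, "epoch_len")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$counts)) +
    ggplot2::geom_col(width = epoch_len * 0.9, fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$axis), ncol = 1) +
    ggplot2::labs(
      x = "time (s)",
      y = sprintf("counts per %d s epoch", epoch_len),
      title = "Epoch activity counts"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a filter magnitude response
#'
#' @param object A `filter_response` tibble from [frequency_response()].
#' @param landmarks Mark the peak and half-gain frequencies?
#' @param ... Unused.
#' @return A ggplot of gain (dB) against frequency on a log axis.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.filter_response <- function(object, landmarks = TRUE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$freq, y = .data$gain_db)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "gain (dB)",
                  title = "Band-pass magnitude response") +
    ggplot2::theme_minimal()
  if (landmarks) {
    lm <- response_landmarks(object)
    vl <- c(lm$lower_halfgain, lm$peak_freq, lm$upper_halfgain)
    p <- p + ggplot2::geom_vline(xintercept = vl, linetype = "dashed",
                                 color = "grey40")
  }
  p
}

#' Plot a pipeline stage walkthrough
#'
#' @param data A long stage tibble from [count_stages()].
#' @return A ggplot with one panel per stage showing each axis over time.
#' @export
plot_stages <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$time, y = .data$value,
                                     color = .data$axis)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$stage), ncol = 1,
                        scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "Raw acceleration through the counts pipeline") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
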