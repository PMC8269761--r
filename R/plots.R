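#' Bland-Altman plot of two paired measurements
#'
#' Mean of the two measurements against their difference, with the bias and
#' limits of agreement as horizontal lines. Convenience wrapper; requires
#' ggplot2.
#'
#' @param x,y Equal-length numeric vectors (same conventions as
#'   [paired_differences()]).
#' @param convention Sign convention passed to [paired_differences()].
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(x, y, convention = "test1_minus_test2") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  d <- paired_differences(x, y, convention)
  ba <- bland_altman(d)
  df <- data.frame(mean = (x + y) / 2, diff = d)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = ba$mean_bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(ba$lower_loa, ba$upper_loa),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of the two measurements (logMAR)",
                  y = "Difference (logMAR)")
}

#' Bar chart of whole-line differences between two tests
#'
#' @param diffs Numeric vector of paired differences (logMAR).
#' @param line_step One line in logMAR. Default 0.1.
#' @return A ggplot object.
#' @export
plot_line_difference_histogram <- function(diffs, line_step = 0.1) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  h <- line_difference_distribution(diffs, line_step)$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = .data$lines, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Difference (lines)", y = "Subjects")
}
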