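#' Plot a mode decomposition
#'
#' One facet per mode showing the reconstructed mode waveform (and
#' optionally the instantaneous amplitude envelope), in the style of a
#' filter-bank decomposition panel.
#'
#' @param object A `tf_decomposition`.
#' @param envelope Overlay the instantaneous amplitude.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tf_decomposition <- function(object, envelope = TRUE, ...) {
  d <- tidy(object)
  d$panel <- factor(paste0("mode ", d$mode, " (", d$frequency, " Hz)"),
                    levels = paste0("mode ", seq_along(object$freqs) - 1,
                                    " (", object$freqs, " Hz)"))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~panel, ncol = 2, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "amplitude (mV)") +
    ggplot2::theme_minimal(base_size = 9)
  if (envelope)
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$amplitude),
                                colour = "firebrick", linewidth = 0.3,
                                alpha = 0.7)
  p
}

#' Plot the Taylor-Fourier filter bank gains
#'
#' Cosine-response magnitude of every mode's order-0 estimator filter over
#' a frequency grid, showing the unit flat bands at each center frequency
#' and the nulls at the other grid frequencies.
#'
#' @param basis A [build_basis()] object.
#' @param f_max Upper frequency limit (Hz).
#' @param df Grid step (Hz).
#' @return A ggplot object.
#' @export
plot_filter_bank <- function(basis, f_max = 50, df = 0.05) {
  fg <- seq(0, f_max, by = df)
  d <- purrr::map(seq_len(basis$n_modes) - 1L, function(j) {
    r <- filter_response(basis, j, fg)
    tibble::tibble(frequency = r$frequency, gain = r$gain,
                   mode = factor(j))
  }) |> purrr::list_rbind()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frequency, y = .data$gain,
                                  colour = .data$mode)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "frequency (Hz)", y = "cosine-response gain",
                  colour = "mode") +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report as a confusion matrix
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  d <- tibble::tibble(
    truth = factor(c("positive", "negative", "negative", "positive"),
                   levels = c("positive", "negative")),
    predicted = factor(c("positive", "positive", "negative", "negative"),
                       levels = c("positive", "negative")),
    count = c(object$tp, object$fp, object$tn, object$fn))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                  fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(
      title = sprintf("Acc %.1f%%  Sen %.1f%%  Spe %.1f%%",
                      object$accuracy, object$sensitivity,
                      object$specificity)) +
    ggplot2::theme_minimal()
}
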