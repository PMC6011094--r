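#' Plot an ECG record
#'
#' @param object An [ecg_record()].
#' @param rpeaks Optional `rpeak_set` to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ecg_record <- function(object, rpeaks = NULL, ...) {
  df <- tibble(time_s = (seq_along(object$samples) - 1L) / object$fs,
               amplitude = object$samples)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = sprintf("amplitude (%s)", object$units),
                  title = object$source_id)
  if (!is.null(rpeaks)) {
    pk <- tibble(time_s = (rpeaks$indices - 1L) / rpeaks$fs,
                 amplitude = object$samples[rpeaks$indices])
    p <- p + ggplot2::geom_point(data = pk, colour = "red", size = 1.2)
  }
  p
}

#' Plot a power spectrum
#' @param object A `power_spectrum`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_spectrum <- function(object, ...) {
  ggplot2::ggplot(tibble(f = object$freqs, p = object$power),
                  ggplot2::aes(.data$f, .data$p)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "power density")
}

#' Plot a decision-threshold ROC curve
#' @param object A `roc_curve_v` from [roc_over_v()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_curve_v <- function(object, ...) {
  best <- attr(object, "best")
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(100 - .data$sp, .data$se)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = df[df$threshold == best, ], colour = "red") +
    ggplot2::coord_equal(xlim = c(0, 100), ylim = c(0, 100)) +
    ggplot2::labs(x = "100 - specificity (%)", y = "sensitivity (%)",
                  title = sprintf("best accuracy at v <= %.2f", best))
}

#' Plot per-fold cross-validation accuracies
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(factor(.data$repeat_i), .data$acc)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "repeat", y = "fold accuracy (%)",
                  title = sprintf("%s: repeated stratified %d-fold CV",
                                  object$method, object$folds))
}
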