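#' Plot a rendered force signal
#'
#' Axial force over insertion depth, coloured by the tissue at the
#' needle tip; puncture peaks and risk events are marked.
#'
#' @param object A `force_signal` from [render_insertion()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.force_signal <- function(object, ...) {
  df <- tibble::as_tibble(object)
  cuts <- dplyr::filter(df, grepl("cut", .data$event))
  ggplot2::ggplot(df, ggplot2::aes(.data$depth_mm, .data$force_N)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$tissue), size = 0.6) +
    ggplot2::geom_point(data = cuts, shape = 4, size = 2, colour = "red") +
    ggplot2::labs(x = "insertion depth [mm]", y = "axial force [N]",
                  colour = "tissue") +
    ggplot2::theme_minimal()
}

#' Plot a per-path error report
#'
#' Distribution of the per-path maximum absolute force error, with
#' flagged top outliers highlighted.
#'
#' @param object A `path_error_report` from [evaluate_paths()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.path_error_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = "paths", y = .data$mae)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.4) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$outlier),
                         width = 0.1, size = 0.7, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = NULL, y = "maximum absolute force error [N]",
                  colour = "outlier") +
    ggplot2::theme_minimal()
}

#' Overlay a reference and a test force signal
#'
#' @param ref,test `force_signal` tibbles on the same depth grid.
#' @return A ggplot object.
#' @export
plot_signal_comparison <- function(ref, test) {
  df <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(ref), model = "reference"),
    dplyr::mutate(tibble::as_tibble(test), model = "test")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$depth_mm, .data$force_N,
                                   colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "insertion depth [mm]", y = "axial force [N]") +
    ggplot2::theme_minimal()
}
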