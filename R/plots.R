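# ggplot2 displays for result objects.

#' @export
autoplot.epee_grid <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "tau", "patience", "accuracy", "speedup"),
    cols = c("accuracy", "speedup"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$patience),
                                     y = factor(.data$tau),
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "patience threshold", y = "entropy threshold",
                  fill = NULL,
                  title = "Accuracy and speed-up across exit-policy settings")
}

#' @export
autoplot.epee_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(object, cols = c("accuracy", "mean_entropy"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$layer, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "exit layer", y = NULL,
                  title = "Per-layer accuracy and mean normalized entropy")
}

#' @export
autoplot.eval_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$layer, y = .data$n_exits)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "exit layer", y = "samples",
                  title = sprintf("Exit-layer distribution (accuracy %.3f, speed-up %.3f)",
                                  object$accuracy, object$speedup))
}
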