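# broom-style tidiers for fitted models and results.

#' @export
tidy.multi_exit_model <- function(x, ...) {
  if (is.null(x$history)) {
    abort("model has no training history; train it first.",
          class = "epee_error_data")
  }
  hist <- x$history
  acc <- purrr::imap(hist$exit_accuracy, function(a, i) {
    tibble::tibble(epoch = hist$epoch[i], exit = seq_along(a), accuracy = a)
  })
  dplyr::left_join(
    dplyr::bind_rows(acc),
    dplyr::select(hist, "epoch", "mean_loss"),
    by = "epoch"
  )
}

#' @export
glance.multi_exit_model <- function(x, ...) {
  cfg <- x$config
  tibble::tibble(
    n_layers = cfg$n_layers,
    hidden_size = cfg$hidden_size,
    n_classes = cfg$n_classes,
    backbone_params = count_parameters(cfg),
    head_params = exit_head_params(cfg),
    head_overhead_pct = exit_head_overhead(cfg),
    epochs_trained = if (is.null(x$history)) 0L else nrow(x$history),
    final_loss = if (is.null(x$history)) NA_real_ else
      x$history$mean_loss[nrow(x$history)]
  )
}
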