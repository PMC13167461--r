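# Deployment modes: budgeted (one fixed exit for every query) and dynamic
# (per-input exit chosen at run time by the policy).  Both operate on one
# instance at a time, mirroring per-request serving with batch size 1.

#' Budgeted-mode prediction
#'
#' Executes exactly `exit_layer` transformer layers and returns the argmax
#' of that layer's exit head.  Layers beyond the budget are never evaluated;
#' `exit_layer = M` reproduces conventional full-depth inference.
#'
#' @param model A `multi_exit_model`.
#' @param tokens Integer token ids for one sample.
#' @param exit_layer The fixed exit m* in \[1, M\].
#' @return The predicted class index.
#' @export
budgeted_predict <- function(model, tokens, exit_layer) {
  stopifnot(inherits(model, "multi_exit_model"))
  M <- model$config$n_layers
  exit_layer <- check_count(exit_layer, "exit_layer")
  if (exit_layer > M) {
    abort("`exit_layer` must be in [1, n_layers].", class = "epee_error_config")
  }
  x <- embed_apply(model, tokens)
  for (m in seq_len(exit_layer)) {
    x <- layer_apply(x, model$par$layers[[m]], model$config$n_heads)
    bump_layer_calls(model)
  }
  argmax_class(head_probs(model, x, exit_layer))
}

#' Dynamic-mode prediction
#'
#' Policy-driven early exit for one sample: delegates to
#' [forward_until_exit()], which evaluates layers sequentially and stops at
#' the first layer where the exit criterion fires.
#'
#' @inheritParams budgeted_predict
#' @param cfg A [policy_config()].
#' @return A list with `predicted_class` and `trace`.
#' @export
dynamic_predict <- function(model, tokens, cfg) {
  forward_until_exit(model, tokens, cfg)
}

# Smallest layer maximizing dev accuracy (ties to the cheapest exit).
pick_best_exit <- function(accuracies) {
  which.max(accuracies)
}

#' Choose a budgeted exit from a development set
#'
#' Profiles every exit head on the labelled development set and returns the
#' smallest layer attaining the maximum accuracy, i.e. the cheapest exit
#' among the best-performing ones.
#'
#' @param model A `multi_exit_model`.
#' @param dev_set A labelled corpus tibble (list-column `tokens`, column
#'   `label`).
#' @return An integer exit layer m*.
#' @export
select_budget_exit <- function(model, dev_set) {
  if (!is.data.frame(dev_set) || nrow(dev_set) == 0L) {
    abort("`dev_set` must be non-empty and labelled.", class = "epee_error_data")
  }
  prof <- per_layer_profile(model, dev_set)
  as.integer(pick_best_exit(prof$accuracy))
}
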