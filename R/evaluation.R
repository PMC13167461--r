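#' Average speed-up ratio
#'
#' One minus the fraction of layer evaluations actually used relative to
#' full-depth inference over a test set:
#' \eqn{1 - \sum_i m_i / (N M)} for exit layers \eqn{m_i}.  0 means every
#' sample ran the full depth; the maximum \eqn{1 - 1/M} is attained when
#' every sample exits at layer 1.  The measure is affine in the mean exit
#' layer and tracks layer-count computational cost.
#'
#' @param exit_layers Integer vector of per-sample exit layers in \[1, M\].
#' @param n_layers Total depth M.
#' @return A number in \[0, 1 - 1/M\].
#' @examples
#' speedup_ratio(c(1, 12), 12) # 1 - 13/24
#' @export
speedup_ratio <- function(exit_layers, n_layers) {
  n_layers <- check_count(n_layers, "n_layers")
  if (length(exit_layers) == 0L) {
    abort("`exit_layers` must be non-empty.", class = "epee_error_data")
  }
  if (any(exit_layers < 1L) || any(exit_layers > n_layers)) {
    abort("exit layers must lie in [1, n_layers].", class = "epee_error_data")
  }
  1 - sum(exit_layers) / (length(exit_layers) * n_layers)
}

new_eval_result <- function(accuracy, exit_layers, n_layers, policy = NULL) {
  structure(
    list(accuracy = accuracy,
         speedup = speedup_ratio(exit_layers, n_layers),
         mean_exit_layer = mean(exit_layers),
         exit_histogram = tabulate(exit_layers, nbins = n_layers),
         n = length(exit_layers),
         n_layers = n_layers,
         policy = policy),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> accuracy %.4f, speed-up %.4f, mean exit %.2f/%d (n=%d)\n",
              x$accuracy, x$speedup, x$mean_exit_layer, x$n_layers, x$n))
  invisible(x)
}

#' Evaluate an exit policy
#'
#' Computes accuracy, speed-up ratio, mean exit layer and the exit-layer
#' histogram for one policy on one labelled dataset.  For a
#' `multi_exit_model` the evaluation runs the true dynamic path
#' ([forward_until_exit()], one instance at a time); for a trajectory tibble
#' (list-column `probs` plus `label`) the policy is applied to the stored
#' per-layer probabilities, which yields identical traces by the two-path
#' equivalence.
#'
#' @param x A `multi_exit_model` or a trajectory tibble.
#' @param ... Method arguments.
#' @return An `eval_result`.
#' @export
evaluate_policy <- function(x, ...) UseMethod("evaluate_policy")

#' @rdname evaluate_policy
#' @param corpus Labelled corpus tibble (for the model method).
#' @param cfg A [policy_config()].
#' @export
evaluate_policy.multi_exit_model <- function(x, corpus, cfg, ...) {
  if (!is.data.frame(corpus) || nrow(corpus) == 0L) {
    abort("`corpus` must be non-empty.", class = "epee_error_data")
  }
  res <- purrr::map(corpus$tokens, function(tk) dynamic_predict(x, tk, cfg))
  exits <- purrr::map_int(res, function(r) r$trace$exit_layer)
  preds <- purrr::map_int(res, "predicted_class")
  new_eval_result(mean(preds == corpus$label), exits,
                  x$config$n_layers, cfg)
}

#' @rdname evaluate_policy
#' @export
evaluate_policy.data.frame <- function(x, cfg, ...) {
  traces <- run_policy_all(x, cfg)
  M <- nrow(x$probs[[1L]])
  new_eval_result(mean(traces$predicted_class == traces$label),
                  traces$exit_layer, M, cfg)
}

#' @export
glance.eval_result <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, speedup = x$speedup,
                 mean_exit_layer = x$mean_exit_layer, n = x$n)
}

#' @export
tidy.eval_result <- function(x, ...) {
  tibble::tibble(layer = seq_len(x$n_layers), n_exits = x$exit_histogram)
}

#' Per-layer accuracy and entropy profile
#'
#' For every exit m in 1..M, the accuracy of the m-th head over the set and
#' the mean normalized entropy of its predictions.  On a trained model the
#' profile typically shows entropy decreasing with depth (deeper predictions
#' are more confident) while accuracy saturates well before the last layer.
#'
#' @param x A `multi_exit_model` or trajectory tibble.
#' @param ... Method arguments.
#' @return A tibble (`layer`, `accuracy`, `mean_entropy`) of class
#'   `epee_profile`.
#' @export
per_layer_profile <- function(x, ...) UseMethod("per_layer_profile")

#' @rdname per_layer_profile
#' @param corpus Labelled corpus tibble (for the model method).
#' @export
per_layer_profile.multi_exit_model <- function(x, corpus, ...) {
  per_layer_profile(collect_trajectories(x, corpus))
}

#' @rdname per_layer_profile
#' @export
per_layer_profile.data.frame <- function(x, ...) {
  if (nrow(x) == 0L) abort("empty data.", class = "epee_error_data")
  M <- nrow(x$probs[[1L]])
  am <- t(vapply(x$probs, function(p) max.col(p, ties.method = "first"),
                 integer(M)))
  en <- t(vapply(x$probs, normalized_entropy, numeric(M)))
  out <- tibble::tibble(
    layer = seq_len(M),
    accuracy = colMeans(am == x$label),
    mean_entropy = colMeans(en)
  )
  class(out) <- c("epee_profile", class(out))
  out
}

# Vectorized first-crossing exit layers for a whole trajectory set, used by
# the grid search.  E: entropies (N x M); R: terminal run lengths (N x M).
grid_exit_layers <- function(E, R, tau, patience) {
  M <- ncol(E)
  ent_hit <- E < tau
  pat_hit <- R >= patience
  hit <- ent_hit | pat_hit
  any_hit <- rowSums(hit) > 0
  first_hit <- max.col(hit, ties.method = "first") # first TRUE where any
  ifelse(any_hit, pmin(first_hit, M), M)
}

#' Grid search over entropy and patience thresholds
#'
#' Evaluates the dynamic mode at every (tau, patience) pair and reports
#' accuracy, speed-up and mean exit layer per cell.  The tau = 0 row
#' reproduces the patience-only method and the patience = M column the
#' entropy-only method, cell for cell.  For a model, trajectories are
#' collected once with [collect_trajectories()] and each policy is applied
#' to them — trace-identical to running the truncated forward pass per cell
#' (two-path equivalence) at a fraction of the cost.
#'
#' @param x A `multi_exit_model` or trajectory tibble.
#' @param ... Method arguments.
#' @return A tibble (`tau`, `patience`, `accuracy`, `speedup`,
#'   `mean_exit_layer`) of class `epee_grid`.
#' @export
grid_search <- function(x, ...) UseMethod("grid_search")

#' @rdname grid_search
#' @param corpus Labelled corpus tibble (for the model method).
#' @param taus Entropy thresholds in \[0, 1\].
#' @param patiences Patience thresholds in \[1, M\].
#' @export
grid_search.multi_exit_model <- function(x, corpus, taus = default_taus(),
                                         patiences = seq_len(x$config$n_layers),
                                         ...) {
  grid_search(collect_trajectories(x, corpus), taus = taus,
              patiences = patiences)
}

#' @rdname grid_search
#' @export
grid_search.data.frame <- function(x, taus = default_taus(),
                                   patiences = NULL, ...) {
  if (nrow(x) == 0L) abort("empty data.", class = "epee_error_data")
  M <- nrow(x$probs[[1L]])
  patiences <- patiences %||% seq_len(M)
  if (any(taus < 0 | taus > 1)) {
    abort("`taus` must lie in [0, 1].", class = "epee_error_config")
  }
  if (any(patiences < 1L | patiences > M)) {
    abort("`patiences` must lie in [1, n_layers].", class = "epee_error_config")
  }
  N <- nrow(x)
  E <- t(vapply(x$probs, normalized_entropy, numeric(M)))
  AM <- t(vapply(x$probs, function(p) max.col(p, ties.method = "first"),
                 integer(M)))
  # terminal run lengths of agreeing argmaxes
  R <- matrix(1L, N, M)
  if (M > 1L) {
    for (m in 2:M) {
      same <- AM[, m] == AM[, m - 1L]
      R[, m] <- ifelse(same, R[, m - 1L] + 1L, 1L)
    }
  }
  cells <- tidyr::expand_grid(tau = as.numeric(taus),
                              patience = as.integer(patiences))
  res <- purrr::pmap(cells, function(tau, patience) {
    exits <- grid_exit_layers(E, R, tau, patience)
    preds <- AM[cbind(seq_len(N), exits)]
    tibble::tibble(accuracy = mean(preds == x$label),
                   speedup = speedup_ratio(exits, M),
                   mean_exit_layer = mean(exits))
  })
  out <- dplyr::bind_cols(cells, dplyr::bind_rows(res))
  attr(out, "n_layers") <- M
  attr(out, "n") <- N
  class(out) <- c("epee_grid", class(out))
  out
}

default_taus <- function() c(0, 0.05, 0.1, 0.2, 0.3, 0.5, 0.7, 1.0)

#' Degeneracy of the hybrid policy
#'
#' Confirms the two limiting cases on data: with tau = 0 the entropy
#' criterion never fires (the test is strict and entropy is non-negative),
#' so hybrid traces must equal patience-only traces element for element;
#' with patience = M the counter \eqn{P_m \le m} can only reach M at the
#' final layer, where exit is unconditional anyway, so hybrid traces must
#' equal entropy-only traces.
#'
#' @param x A `multi_exit_model` or trajectory tibble.
#' @param ... Method arguments.
#' @return A list with logicals `patience_equivalent` and
#'   `entropy_equivalent`.
#' @export
degeneracy_check <- function(x, ...) UseMethod("degeneracy_check")

#' @rdname degeneracy_check
#' @param corpus Labelled corpus tibble (for the model method).
#' @param tau Entropy threshold used for the entropy-only comparison.
#' @param patience Patience threshold used for the patience-only comparison.
#' @export
degeneracy_check.multi_exit_model <- function(x, corpus, tau = 0.2,
                                              patience = 3L, ...) {
  M <- x$config$n_layers
  run_traces <- function(cfg) {
    purrr::map(corpus$tokens, function(tk) forward_until_exit(x, tk, cfg)$trace)
  }
  list(
    patience_equivalent = identical(
      run_traces(policy_config("epee", tau = 0, patience = patience)),
      run_traces(policy_config("patience", patience = patience))
    ),
    entropy_equivalent = identical(
      run_traces(policy_config("epee", tau = tau, patience = M)),
      run_traces(policy_config("entropy", tau = tau))
    )
  )
}

#' @rdname degeneracy_check
#' @export
degeneracy_check.data.frame <- function(x, tau = 0.2, patience = 3L, ...) {
  M <- nrow(x$probs[[1L]])
  tr <- function(cfg) run_policy_all(x, cfg)
  list(
    patience_equivalent = identical(
      tr(policy_config("epee", tau = 0, patience = patience)),
      tr(policy_config("patience", patience = patience))
    ),
    entropy_equivalent = identical(
      tr(policy_config("epee", tau = tau, patience = M)),
      tr(policy_config("entropy", tau = tau))
    )
  )
}
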