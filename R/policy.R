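#' Exit policy configuration
#'
#' An exit policy decides, layer by layer, whether a multi-exit classifier
#' should stop and emit the current prediction.  The hybrid (`"epee"`) policy
#' exits at the first layer where either the normalized prediction entropy
#' falls strictly below `tau` or the patience counter (run length of
#' consecutive layers agreeing on the argmax class) reaches `patience`.  The
#' two classic single-criterion policies are exact special cases and are
#' resolved that way internally: `mode = "entropy"` behaves as `"epee"` with
#' an effective patience threshold of M (the number of layers, only known at
#' decision time), and `mode = "patience"` behaves as `"epee"` with
#' `tau = 0`, which never fires because the entropy test is strict.
#'
#' @param mode One of `"epee"`, `"entropy"`, `"patience"`.
#' @param tau Entropy threshold \eqn{\tau} in \[0, 1\].  Ignored when
#'   `mode = "patience"`.
#' @param patience Patience threshold \eqn{P_t}, a positive integer.  Ignored
#'   when `mode = "entropy"`.
#' @return A `policy_config` object.
#' @examples
#' policy_config("epee", tau = 0.2, patience = 3)
#' policy_config("entropy", tau = 0.1)
#' @export
policy_config <- function(mode = c("epee", "entropy", "patience"),
                          tau = 0.2, patience = 3L) {
  mode <- match.arg(mode)
  tau <- check_fraction(tau, "tau")
  patience <- check_count(patience, "patience")
  structure(list(mode = mode, tau = tau, patience = patience),
            class = "policy_config")
}

#' @export
print.policy_config <- function(x, ...) {
  cat("<policy_config> mode =", x$mode)
  if (x$mode != "patience") cat(", tau =", x$tau)
  if (x$mode != "entropy") cat(", patience =", x$patience)
  cat("\n")
  invisible(x)
}

# Effective (tau, patience) pair for a given depth M.  The single-criterion
# modes are degenerate parameterizations of the hybrid rule.
resolve_policy <- function(cfg, n_layers) {
  stopifnot(inherits(cfg, "policy_config"))
  n_layers <- check_count(n_layers, "n_layers")
  tau <- if (cfg$mode == "patience") 0 else cfg$tau
  pt <- if (cfg$mode == "entropy") n_layers else cfg$patience
  if (pt > n_layers) {
    abort("`patience` must not exceed the number of layers.",
          class = "epee_error_config")
  }
  list(tau = tau, patience = as.integer(pt))
}

#' Normalized prediction entropy
#'
#' Shannon entropy of a class-probability vector divided by \eqn{\log K}, a
#' base-invariant confidence score in \[0, 1\]: 0 for a one-hot prediction,
#' 1 for the uniform distribution.  Lower means more confident.  The
#' convention \eqn{0 \log 0 = 0} applies; the natural logarithm is used
#' internally (the normalization makes the base immaterial).
#'
#' @param p A probability vector over K >= 2 classes, or a layers-by-classes
#'   matrix (one vector per row).
#' @return A number in \[0, 1\], or a vector of them for matrix input.
#' @examples
#' normalized_entropy(rep(0.25, 4)) # 1
#' normalized_entropy(c(1, 0, 0)) # 0
#' normalized_entropy(c(0.5, 0.5, 0, 0)) # 0.5
#' @export
normalized_entropy <- function(p) {
  if (is.matrix(p)) {
    check_prob_matrix(p)
    return(vapply(seq_len(nrow(p)), function(m) normalized_entropy(p[m, ]),
                  numeric(1)))
  }
  check_prob_vector(p)
  pos <- p > 0
  h <- -sum(p[pos] * log(p[pos])) / log(length(p))
  # Clamp float droop so downstream range checks are exact.
  min(max(h, 0), 1)
}

#' Argmax class of a probability vector
#'
#' Returns the (1-based) index of the largest entry; ties are broken
#' deterministically to the lowest index.
#'
#' @param p A probability vector.
#' @return An integer class index.
#' @examples
#' argmax_class(c(0.1, 0.7, 0.2)) # 2
#' argmax_class(c(0.4, 0.4, 0.2)) # 1 (tie to lowest index)
#' @export
argmax_class <- function(p) {
  if (!is.numeric(p) || length(p) < 1L) {
    abort("`p` must be a non-empty numeric vector.",
          class = "epee_error_distribution")
  }
  which.max(p)
}

#' Update the patience counter
#'
#' The patience counter tracks how many consecutive layers have agreed on
#' the argmax class.  A first observation starts a run of length 1; agreement
#' with the previous layer increments the counter; disagreement resets it
#' to 1.
#'
#' @param state A list with fields `count` (integer) and `last_class`
#'   (integer class index, or `NA` before any prediction).  Use
#'   `patience_state()` for the initial state.
#' @param current_class Class index predicted at the current layer.
#' @return The updated state.
#' @examples
#' s <- patience_state()
#' s <- update_patience(s, 3L) # count 1
#' s <- update_patience(s, 3L) # count 2
#' s <- update_patience(s, 1L) # reset to 1
#' @export
update_patience <- function(state, current_class) {
  current_class <- check_count(current_class, "current_class")
  count <- if (!is.na(state$last_class) && state$last_class == current_class) {
    state$count + 1L
  } else {
    1L
  }
  list(count = count, last_class = current_class)
}

#' @rdname update_patience
#' @export
patience_state <- function() list(count = 0L, last_class = NA_integer_)

#' Per-layer exit decision
#'
#' Exit fires iff the normalized entropy is strictly below the effective
#' entropy threshold, or the patience counter has reached the effective
#' patience threshold, or the final layer has been reached (the last exit
#' always emits, irrespective of its confidence).
#'
#' @param entropy Normalized entropy at the current layer, in \[0, 1\].
#' @param patience_count Current patience counter (>= 1).
#' @param layer Current layer index in \[1, `n_layers`\].
#' @param cfg A [policy_config()].
#' @param n_layers Total number of layers M.
#' @return `"exit"` or `"continue"`.
#' @export
decide_exit <- function(entropy, patience_count, layer, cfg, n_layers) {
  n_layers <- check_count(n_layers, "n_layers")
  layer <- check_count(layer, "layer")
  if (layer > n_layers) {
    abort("`layer` must be in [1, n_layers].", class = "epee_error_layer")
  }
  eff <- resolve_policy(cfg, n_layers)
  fired <- entropy < eff$tau || patience_count >= eff$patience || layer == n_layers
  if (fired) "exit" else "continue"
}

new_exit_trace <- function(exit_layer, predicted_class, trigger,
                           entropies, patience_counts) {
  structure(
    list(exit_layer = as.integer(exit_layer),
         predicted_class = as.integer(predicted_class),
         trigger = trigger,
         entropies = as.numeric(entropies),
         patience_counts = as.integer(patience_counts)),
    class = "exit_trace"
  )
}

#' @export
print.exit_trace <- function(x, ...) {
  cat(sprintf("<exit_trace> layer %d, class %d, trigger %s\n",
              x$exit_layer, x$predicted_class, x$trigger))
  cat("  H:", paste(sprintf("%.3f", x$entropies), collapse = " "), "\n")
  cat("  P:", paste(x$patience_counts, collapse = " "), "\n")
  invisible(x)
}

# Classify what fired at the exit layer.
exit_trigger <- function(entropy_fired, patience_fired, at_final) {
  if (entropy_fired && patience_fired) "both"
  else if (entropy_fired) "entropy"
  else if (patience_fired) "patience"
  else if (at_final) "final_layer"
  else abort("internal: no criterion fired before the final layer")
}

#' Run an exit policy over one probability trajectory
#'
#' Scans layers 1..M in order: computes the normalized entropy, updates the
#' patience counter, and applies the exit decision.  The returned trace is
#' truncated at the exit layer; the prediction is the argmax of the exit
#' layer's probability vector.
#'
#' @param probs A layers-by-classes matrix: row m is the probability vector
#'   emitted by the exit head at layer m.
#' @param cfg A [policy_config()].
#' @return An `exit_trace` with fields `exit_layer`, `predicted_class`,
#'   `trigger` (`"entropy"`, `"patience"`, `"both"` or `"final_layer"`),
#'   `entropies` and `patience_counts` (both of length `exit_layer`).
#' @examples
#' probs <- rbind(c(0.4, 0.35, 0.25), c(0.5, 0.3, 0.2), c(0.96, 0.02, 0.02))
#' run_policy(probs, policy_config("epee", tau = 0.25, patience = 2))
#' @export
run_policy <- function(probs, cfg) {
  check_prob_matrix(probs)
  M <- nrow(probs)
  eff <- resolve_policy(cfg, M)

  entropies <- numeric(M)
  counts <- integer(M)
  state <- patience_state()
  for (m in seq_len(M)) {
    entropies[m] <- normalized_entropy(probs[m, ])
    state <- update_patience(state, argmax_class(probs[m, ]))
    counts[m] <- state$count
    entropy_fired <- entropies[m] < eff$tau
    patience_fired <- counts[m] >= eff$patience
    if (entropy_fired || patience_fired || m == M) {
      return(new_exit_trace(
        exit_layer = m,
        predicted_class = argmax_class(probs[m, ]),
        trigger = exit_trigger(entropy_fired, patience_fired, m == M),
        entropies = entropies[seq_len(m)],
        patience_counts = counts[seq_len(m)]
      ))
    }
  }
}

#' Brute-force exit-layer reference
#'
#' Independent re-derivation of the exit layer used to cross-check
#' [run_policy()]: for each layer m it recomputes the entropy directly from
#' the definition and the terminal run length of agreeing argmaxes by
#' scanning backwards from m, without any carried state.  Intended for
#' testing; quadratic in the number of layers.
#'
#' @inheritParams run_policy
#' @return The exit layer, an integer in \[1, M\].
#' @export
exit_layer_oracle <- function(probs, cfg) {
  check_prob_matrix(probs)
  M <- nrow(probs)
  eff <- resolve_policy(cfg, M)
  K <- ncol(probs)
  for (m in seq_len(M)) {
    p <- probs[m, ]
    pos <- p > 0
    h <- -sum(p[pos] * log(p[pos])) / log(K)
    # Terminal run length of identical argmaxes ending at layer m.
    run <- 1L
    j <- m
    while (j > 1L &&
           which.max(probs[j - 1L, ]) == which.max(probs[j, ])) {
      run <- run + 1L
      j <- j - 1L
    }
    if (h < eff$tau || run >= eff$patience) return(m)
  }
  M
}

#' Apply an exit policy to a set of trajectories
#'
#' Tidy wrapper over [run_policy()]: one input row per sample, one output
#' row per sample with the trace unpacked into columns.
#'
#' @param data A tibble with a list-column `probs` of layers-by-classes
#'   matrices and (optionally) a `label` column; as produced by
#'   [generate_trajectories()] or [collect_trajectories()].
#' @param cfg A [policy_config()].
#' @return A tibble with columns `id`, `label` (if present), `exit_layer`,
#'   `predicted_class`, `trigger`, and list-columns `entropies`,
#'   `patience_counts`.
#' @export
run_policy_all <- function(data, cfg) {
  if (!is.data.frame(data) || !"probs" %in% names(data)) {
    abort("`data` must be a data frame with a `probs` list-column.",
          class = "epee_error_trajectory")
  }
  traces <- purrr::map(data$probs, run_policy, cfg = cfg)
  out <- tibble::tibble(
    id = if ("id" %in% names(data)) data$id else seq_len(nrow(data)),
    exit_layer = purrr::map_int(traces, "exit_layer"),
    predicted_class = purrr::map_int(traces, "predicted_class"),
    trigger = purrr::map_chr(traces, "trigger"),
    entropies = purrr::map(traces, "entropies"),
    patience_counts = purrr::map(traces, "patience_counts")
  )
  if ("label" %in% names(data)) {
    out <- dplyr::mutate(out, label = data$label, .after = "id")
  }
  out
}
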