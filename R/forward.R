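# Single-sample forward pass (inference path).  The batched training path
# with gradient caches lives in backprop.R; the two share the same
# parameterization and are cross-checked in tests.

ln_apply <- function(x, ln, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  sweep(xhat, 2L, ln$g, `*`) + matrix(ln$b, nrow(x), length(ln$b), byrow = TRUE)
}

attn_apply <- function(x, attn, n_heads) {
  d <- ncol(x)
  dh <- d %/% n_heads
  Tn <- nrow(x)
  Q <- x %*% attn$Wq + matrix(attn$bq, Tn, d, byrow = TRUE)
  K <- x %*% attn$Wk + matrix(attn$bk, Tn, d, byrow = TRUE)
  V <- x %*% attn$Wv + matrix(attn$bv, Tn, d, byrow = TRUE)
  O <- matrix(0, Tn, d)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    S <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) / sqrt(dh)
    P <- softmax_rows(S)
    O[, cols] <- P %*% V[, cols, drop = FALSE]
  }
  O %*% attn$Wo + matrix(attn$bo, Tn, d, byrow = TRUE)
}

# One pre-norm transformer block: x + Attn(LN1(x)); then x + FFN(LN2(x)).
layer_apply <- function(x, lp, n_heads) {
  x <- x + attn_apply(ln_apply(x, lp$ln1), lp$attn, n_heads)
  h <- ln_apply(x, lp$ln2)
  a <- pmax(h %*% lp$ffn$W1 +
              matrix(lp$ffn$b1, nrow(h), length(lp$ffn$b1), byrow = TRUE), 0)
  x + a %*% lp$ffn$W2 + matrix(lp$ffn$b2, nrow(h), ncol(x), byrow = TRUE)
}

embed_apply <- function(model, tokens) {
  cfg <- model$config
  par <- model$par
  tokens <- as.integer(tokens)
  if (length(tokens) < 1L) {
    abort("`tokens` must be non-empty.", class = "epee_error_input")
  }
  if (any(tokens < 1L) || any(tokens > cfg$vocab_size)) {
    abort("token id out of vocabulary.", class = "epee_error_input")
  }
  if (length(tokens) > cfg$max_positions) {
    abort("sequence longer than `max_positions`.", class = "epee_error_input")
  }
  x <- par$tok[tokens, , drop = FALSE] +
    par$pos[seq_along(tokens), , drop = FALSE]
  if (!is.null(par$type)) {
    x <- x + matrix(par$type[1L, ], nrow(x), ncol(x), byrow = TRUE)
  }
  if (!is.null(par$ln_e)) x <- ln_apply(x, par$ln_e)
  x
}

pool_state <- function(x, pooling) {
  switch(pooling,
         mean = colMeans(x),
         first_token = x[1L, ],
         last_token = x[nrow(x), ],
         abort("unknown pooling rule", class = "epee_error_config"))
}

head_probs <- function(model, x, m) {
  par <- model$par
  if (!is.null(par$ln_f) && m == model$config$n_layers) {
    x <- ln_apply(x, par$ln_f)
  }
  s <- pool_state(x, model$config$pooling)
  if (!is.null(par$pooler)) {
    s <- tanh(drop(s %*% par$pooler$W) + par$pooler$b)
  }
  h <- par$heads[[m]]
  softmax_vec(drop(s %*% h$W) + h$b)
}

#' Per-layer class probabilities for one sample
#'
#' Runs the full backbone and returns the probability vector emitted by
#' every exit head: row m is softmax of the m-th head applied to the pooled
#' hidden state after layer m.  Used for training-style evaluation, budgeted
#' profiling and trajectory collection.
#'
#' @param model A `multi_exit_model`.
#' @param tokens Integer token ids (1-based, within the vocabulary).
#' @return An M-by-K probability matrix.
#' @export
forward_all_exits <- function(model, tokens) {
  stopifnot(inherits(model, "multi_exit_model"))
  cfg <- model$config
  x <- embed_apply(model, tokens)
  probs <- matrix(NA_real_, cfg$n_layers, cfg$n_classes)
  for (m in seq_len(cfg$n_layers)) {
    x <- layer_apply(x, model$par$layers[[m]], cfg$n_heads)
    bump_layer_calls(model)
    probs[m, ] <- head_probs(model, x, m)
  }
  probs
}

#' Early-exit forward pass for one sample
#'
#' Evaluates transformer layers strictly sequentially, reusing the hidden
#' state from layer to layer, and applies the exit policy after each layer.
#' No layer beyond the exit layer is executed (verifiable via
#' [layer_calls()]).
#'
#' @inheritParams forward_all_exits
#' @param cfg A [policy_config()].
#' @return A list with `predicted_class` and `trace` (an `exit_trace`).
#' @export
forward_until_exit <- function(model, tokens, cfg) {
  stopifnot(inherits(model, "multi_exit_model"))
  mcfg <- model$config
  M <- mcfg$n_layers
  eff <- resolve_policy(cfg, M)
  x <- embed_apply(model, tokens)
  entropies <- numeric(0)
  counts <- integer(0)
  state <- patience_state()
  for (m in seq_len(M)) {
    x <- layer_apply(x, model$par$layers[[m]], mcfg$n_heads)
    bump_layer_calls(model)
    p <- head_probs(model, x, m)
    entropies[m] <- normalized_entropy(p)
    state <- update_patience(state, argmax_class(p))
    counts[m] <- state$count
    entropy_fired <- entropies[m] < eff$tau
    patience_fired <- counts[m] >= eff$patience
    if (entropy_fired || patience_fired || m == M) {
      trace <- new_exit_trace(
        exit_layer = m,
        predicted_class = argmax_class(p),
        trigger = exit_trigger(entropy_fired, patience_fired, m == M),
        entropies = entropies,
        patience_counts = counts
      )
      return(list(predicted_class = trace$predicted_class, trace = trace))
    }
  }
}

#' Collect per-layer probability trajectories for a corpus
#'
#' Runs [forward_all_exits()] on every record and returns a tibble ready for
#' the trajectory-level evaluation functions ([run_policy_all()],
#' [grid_search()], [per_layer_profile()], ...).
#'
#' @param model A `multi_exit_model`.
#' @param corpus A tibble with list-column `tokens` and column `label`, as
#'   produced by [generate_corpus()].
#' @return A tibble with columns `id`, `label` and list-column `probs`.
#' @export
collect_trajectories <- function(model, corpus) {
  stopifnot(is.data.frame(corpus), "tokens" %in% names(corpus))
  tibble::tibble(
    id = if ("id" %in% names(corpus)) corpus$id else seq_len(nrow(corpus)),
    label = corpus$label,
    probs = purrr::map(corpus$tokens, function(tk) forward_all_exits(model, tk))
  )
}
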