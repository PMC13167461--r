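#' Multi-exit backbone geometry
#'
#' Describes a transformer backbone with an affine exit head after every
#' layer.  The default geometry is a tiny pre-norm encoder (6 layers, width
#' 64) that trains from scratch on a CPU in seconds; the preset constructors
#' reproduce published base geometries for parameter accounting.
#'
#' @param n_layers Number of transformer layers M (one exit head each).
#' @param hidden_size Model width d.
#' @param n_heads Number of attention heads; must divide `hidden_size`.
#' @param ffn_size Width of the position-wise feed-forward inner layer.
#' @param vocab_size Token vocabulary size (>= 2).
#' @param max_positions Maximum sequence length (learned position embeddings).
#' @param n_token_types Number of segment/token-type embeddings (0 for none).
#' @param n_classes Number of target classes K (>= 2).
#' @param pooling How a sequence of hidden states is reduced to one vector
#'   before an exit head: `"mean"`, `"first_token"`, or `"last_token"`.
#' @param include_pooler Include a dense+tanh pooler between the pooled
#'   hidden state and the exit heads (encoder convention).
#' @param embed_layernorm Layer-normalize the summed embeddings (encoder
#'   convention).
#' @param final_layernorm Apply a final layer norm after the last layer
#'   (decoder convention).
#' @return A `multi_exit_config` object.
#' @examples
#' cfg <- multi_exit_config()
#' count_parameters(cfg)
#' exit_head_overhead(cfg)
#' @export
multi_exit_config <- function(n_layers = 6L, hidden_size = 64L, n_heads = 4L,
                              ffn_size = 128L, vocab_size = 64L,
                              max_positions = 32L, n_token_types = 0L,
                              n_classes = 4L,
                              pooling = c("mean", "first_token", "last_token"),
                              include_pooler = FALSE,
                              embed_layernorm = TRUE,
                              final_layernorm = FALSE) {
  pooling <- match.arg(pooling)
  n_layers <- check_count(n_layers, "n_layers")
  hidden_size <- check_count(hidden_size, "hidden_size")
  n_heads <- check_count(n_heads, "n_heads")
  ffn_size <- check_count(ffn_size, "ffn_size")
  vocab_size <- check_count(vocab_size, "vocab_size", min = 2L)
  max_positions <- check_count(max_positions, "max_positions")
  n_token_types <- check_count(n_token_types, "n_token_types", min = 0L)
  n_classes <- check_count(n_classes, "n_classes", min = 2L)
  if (hidden_size %% n_heads != 0L) {
    abort("`n_heads` must divide `hidden_size`.", class = "epee_error_config")
  }
  structure(
    list(n_layers = n_layers, hidden_size = hidden_size, n_heads = n_heads,
         ffn_size = ffn_size, vocab_size = vocab_size,
         max_positions = max_positions, n_token_types = n_token_types,
         n_classes = n_classes, pooling = pooling,
         include_pooler = isTRUE(include_pooler),
         embed_layernorm = isTRUE(embed_layernorm),
         final_layernorm = isTRUE(final_layernorm)),
    class = "multi_exit_config"
  )
}

#' @export
print.multi_exit_config <- function(x, ...) {
  cat(sprintf("<multi_exit_config> M=%d d=%d heads=%d ffn=%d vocab=%d K=%d pooling=%s\n",
              x$n_layers, x$hidden_size, x$n_heads, x$ffn_size,
              x$vocab_size, x$n_classes, x$pooling))
  cat(sprintf("  backbone parameters: %s (+ %s exit-head)\n",
              format(count_parameters(x), big.mark = ","),
              format(exit_head_params(x), big.mark = ",")))
  invisible(x)
}

#' @rdname multi_exit_config
#' @param n_classes_at Number of classes for the preset's exit heads.
#' @details
#' `config_encoder_base()` is the published 12-layer, 768-wide bidirectional
#' encoder geometry (30,522-token WordPiece vocabulary, 512 positions, two
#' token types, embedding layer norm, dense+tanh pooler): 109,482,240
#' backbone parameters, i.e. 109M truncated to millions.
#' `config_decoder_base()` is the published 12-layer, 768-wide causal
#' decoder geometry (50,257-token BPE vocabulary, 1,024 positions, tied
#' output embedding, final layer norm): 124,439,808 parameters, 124M.
#' @export
config_encoder_base <- function(n_classes_at = 2L) {
  multi_exit_config(
    n_layers = 12L, hidden_size = 768L, n_heads = 12L, ffn_size = 3072L,
    vocab_size = 30522L, max_positions = 512L, n_token_types = 2L,
    n_classes = n_classes_at, pooling = "first_token",
    include_pooler = TRUE, embed_layernorm = TRUE, final_layernorm = FALSE
  )
}

#' @rdname multi_exit_config
#' @export
config_decoder_base <- function(n_classes_at = 2L) {
  multi_exit_config(
    n_layers = 12L, hidden_size = 768L, n_heads = 12L, ffn_size = 3072L,
    vocab_size = 50257L, max_positions = 1024L, n_token_types = 0L,
    n_classes = n_classes_at, pooling = "last_token",
    include_pooler = FALSE, embed_layernorm = FALSE, final_layernorm = TRUE
  )
}

#' Backbone parameter count
#'
#' Closed-form count of trainable backbone parameters (exit heads excluded):
#' token, position and token-type embeddings, per-layer attention
#' (four d-by-d projections with biases), two layer norms and the
#' feed-forward block, plus the optional embedding layer norm, pooler and
#' final layer norm.  For an instantiated model the tally is taken over the
#' allocated arrays; the two agree exactly.
#'
#' @param x A `multi_exit_config` or `multi_exit_model`.
#' @param ... Unused.
#' @return Parameter count (a double, since counts exceed integer range for
#'   large geometries is not an issue here but consistency is cheap).
#' @examples
#' count_parameters(config_encoder_base()) # 109482240
#' count_parameters(config_decoder_base()) # 124439808
#' @export
count_parameters <- function(x, ...) UseMethod("count_parameters")

#' @export
count_parameters.multi_exit_config <- function(x, ...) {
  d <- x$hidden_size
  f <- x$ffn_size
  emb <- x$vocab_size * d + x$max_positions * d + x$n_token_types * d +
    if (x$embed_layernorm) 2 * d else 0
  per_layer <- 4 * (d * d + d) +  # Q, K, V, output projections
    2 * d +                       # attention layer norm
    (d * f + f) + (f * d + d) +   # feed-forward in/out
    2 * d                         # feed-forward layer norm
  extras <- (if (x$include_pooler) d * d + d else 0) +
    (if (x$final_layernorm) 2 * d else 0)
  as.numeric(emb + x$n_layers * per_layer + extras)
}

#' @export
count_parameters.multi_exit_model <- function(x, ...) {
  tally <- function(p) {
    if (is.null(p)) 0
    else if (is.list(p)) sum(vapply(p, tally, numeric(1)))
    else length(p)
  }
  backbone <- x$par[setdiff(names(x$par), "heads")]
  as.numeric(tally(backbone))
}

#' @rdname exit_head_overhead
#' @export
exit_head_params <- function(cfg) {
  stopifnot(inherits(cfg, "multi_exit_config"))
  with(cfg, as.numeric(n_layers * (hidden_size * n_classes + n_classes)))
}

#' Exit-head parameter overhead
#'
#' Adding an affine K-class head at each of the M layers costs
#' M (dK + K) parameters.  The overhead is that count as a percentage of the
#' total (backbone plus heads); for published base geometries it is well
#' under 3 percent.
#'
#' @param cfg A `multi_exit_config`.
#' @return `exit_head_params()`: the added parameter count.
#'   `exit_head_overhead()`: the overhead percentage in \[0, 100\].
#' @examples
#' exit_head_overhead(config_encoder_base(n_classes_at = 9L)) # ~0.076
#' @export
exit_head_overhead <- function(cfg) {
  hp <- exit_head_params(cfg)
  100 * hp / (count_parameters(cfg) + hp)
}

#' Instantiate a multi-exit model
#'
#' Allocates and deterministically initializes all backbone and exit-head
#' parameters under `seed`: weights from N(0, 0.02^2), biases zero, layer
#' norm gains one.  The model exposes layer-wise evaluation so inference can
#' stop at any layer; an internal counter records how many layer evaluations
#' have been performed (used to verify truncation contracts).
#'
#' @param cfg A `multi_exit_config`.
#' @param seed Integer seed for the initialization.
#' @return A `multi_exit_model` object.
#' @export
build_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "multi_exit_config"))
  seed <- check_count(seed, "seed", min = 0L)
  d <- cfg$hidden_size
  init <- function(nr, nc) matrix(rnorm(nr * nc, sd = 0.02), nr, nc)
  ln_par <- function() list(g = rep(1, d), b = rep(0, d))
  par <- withr::with_seed(seed, {
    list(
      tok = init(cfg$vocab_size, d),
      pos = init(cfg$max_positions, d),
      type = if (cfg$n_token_types > 0L) init(cfg$n_token_types, d) else NULL,
      ln_e = if (cfg$embed_layernorm) ln_par() else NULL,
      layers = purrr::map(seq_len(cfg$n_layers), function(m) {
        list(
          ln1 = ln_par(),
          attn = list(Wq = init(d, d), bq = rep(0, d),
                      Wk = init(d, d), bk = rep(0, d),
                      Wv = init(d, d), bv = rep(0, d),
                      Wo = init(d, d), bo = rep(0, d)),
          ln2 = ln_par(),
          ffn = list(W1 = init(d, cfg$ffn_size), b1 = rep(0, cfg$ffn_size),
                     W2 = init(cfg$ffn_size, d), b2 = rep(0, d))
        )
      }),
      pooler = if (cfg$include_pooler) list(W = init(d, d), b = rep(0, d)) else NULL,
      ln_f = if (cfg$final_layernorm) ln_par() else NULL,
      heads = purrr::map(seq_len(cfg$n_layers), function(m) {
        list(W = init(d, cfg$n_classes), b = rep(0, cfg$n_classes))
      })
    )
  })
  structure(
    list(config = cfg, par = par, seed = seed,
         counter = new.env(parent = emptyenv()),
         history = NULL),
    class = "multi_exit_model"
  )
}

#' @export
print.multi_exit_model <- function(x, ...) {
  cat(sprintf("<multi_exit_model> %d layers, width %d, %d classes%s\n",
              x$config$n_layers, x$config$hidden_size, x$config$n_classes,
              if (is.null(x$history)) " (untrained)" else " (trained)"))
  print(x$config)
  invisible(x)
}

#' Layer-evaluation counter
#'
#' Every transformer-layer evaluation increments an internal counter.
#' `layer_calls()` reads it and `reset_layer_calls()` zeroes it; tests use
#' the counter to assert that early-exit inference never evaluates a layer
#' past the exit layer.
#'
#' @param model A `multi_exit_model`.
#' @return `layer_calls()`: the number of layer evaluations since the last
#'   reset.
#' @export
layer_calls <- function(model) {
  n <- model$counter$n
  if (is.null(n)) 0L else n
}

#' @rdname layer_calls
#' @export
reset_layer_calls <- function(model) {
  assign("n", 0L, envir = model$counter)
  invisible(model)
}

bump_layer_calls <- function(model, by = 1L) {
  assign("n", layer_calls(model) + as.integer(by), envir = model$counter)
  invisible(model)
}
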