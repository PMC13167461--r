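#' Generate a synthetic labelled token corpus
#'
#' Seeded generator for a K-class sequence-classification corpus with a
#' controllable easy/hard difficulty mixture.  Token ids 1..K are reserved
#' as class-evidence tokens (token k is evidence for class k); the remaining
#' vocabulary is uninformative background.  An *easy* record carries
#' `evidence_strength` copies of its own class's evidence token in the
#' earliest positions; a *hard* record carries a single evidence token at a
#' random position and, half the time, one distractor evidence token of
#' another class.  Labels are balanced within one count per class and the
#' label of every easy record is recoverable by the bag-of-evidence rule
#' [evidence_rule_predict()].
#'
#' @param n_samples Number of records N.
#' @param n_classes Number of classes K (>= 2).
#' @param seq_length Length of every token sequence.
#' @param vocab_size Vocabulary size; must exceed `n_classes` so background
#'   tokens exist.
#' @param easy_fraction Fraction of records generated as easy.
#' @param evidence_strength Number of evidence tokens in an easy record.
#' @param seed Seed; the generator is deterministic given the spec.
#' @return A tibble (`id`, `tokens` list-column, `label`, `difficulty`).
#' @examples
#' corpus <- generate_corpus(n_samples = 20, seed = 1)
#' table(corpus$label)
#' @export
generate_corpus <- function(n_samples = 2000L, n_classes = 4L,
                            seq_length = 16L, vocab_size = 64L,
                            easy_fraction = 0.5, evidence_strength = 3L,
                            seed = 1L) {
  n_samples <- check_count(n_samples, "n_samples")
  n_classes <- check_count(n_classes, "n_classes", min = 2L)
  seq_length <- check_count(seq_length, "seq_length")
  vocab_size <- check_count(vocab_size, "vocab_size", min = 2L)
  easy_fraction <- check_fraction(easy_fraction, "easy_fraction")
  evidence_strength <- check_count(evidence_strength, "evidence_strength")
  seed <- check_count(seed, "seed", min = 0L)
  if (vocab_size <= n_classes) {
    abort("`vocab_size` must exceed `n_classes` (one evidence token per class plus background).",
          class = "epee_error_config")
  }
  if (evidence_strength > seq_length) {
    abort("`evidence_strength` must not exceed `seq_length`.",
          class = "epee_error_config")
  }
  background <- function(n) sample((n_classes + 1L):vocab_size, n, replace = TRUE)
  withr::with_seed(seed, {
    labels <- rep_len(seq_len(n_classes), n_samples)[sample.int(n_samples)]
    n_easy <- round(easy_fraction * n_samples)
    easy <- seq_len(n_samples) %in% sample.int(n_samples, n_easy)
    tokens <- purrr::map(seq_len(n_samples), function(i) {
      tk <- background(seq_length)
      if (easy[i]) {
        tk[seq_len(evidence_strength)] <- labels[i]
      } else {
        tk[sample.int(seq_length, 1L)] <- labels[i]
        if (stats::runif(1) < 0.5) {
          other <- sample(setdiff(seq_len(n_classes), labels[i]), 1L)
          free <- which(tk > n_classes)
          if (length(free)) tk[free[sample.int(length(free), 1L)]] <- other
        }
      }
      as.integer(tk)
    })
    tibble::tibble(
      id = seq_len(n_samples),
      tokens = tokens,
      label = as.integer(labels),
      difficulty = ifelse(easy, "easy", "hard")
    )
  })
}

#' Bag-of-evidence decision rule
#'
#' The generating rule's own classifier: counts evidence tokens (ids 1..K)
#' in a sequence and predicts the class with the highest count, ties broken
#' to the lowest index.  Serves as a construction oracle for the corpus
#' generator: easy records are classified correctly by design.
#'
#' @param tokens Integer token ids.
#' @param n_classes Number of classes K.
#' @return Predicted class index.
#' @export
evidence_rule_predict <- function(tokens, n_classes) {
  counts <- tabulate(tokens[tokens <= n_classes], nbins = n_classes)
  which.max(counts)
}

#' Generate model-free per-layer probability trajectories
#'
#' Statistical stand-in for the per-layer outputs of a trained multi-exit
#' model: for each sample the logit of its signal class grows linearly with
#' depth at `convergence_rate` while every logit receives independent
#' Gaussian noise of scale `noise_scale`, and the layer-m probability vector
#' is the softmax of the layer-m logits.  Expected normalized entropy
#' therefore decreases with depth — the empirical pattern in trained
#' multi-exit transformers.  `label_flip_rate` makes the trajectory of a
#' sample converge to a *wrong* class with that probability, injecting
#' irreducible error so accuracy ceilings below 1 are exercised.
#'
#' @param n_samples Number of trajectories.
#' @param n_layers Depth M.
#' @param n_classes Number of classes K.
#' @param convergence_rate Per-layer growth of the signal-class logit
#'   (> 0 for entropy to decline; 0 gives depth-constant distributions).
#' @param noise_scale Standard deviation of the logit noise (>= 0).
#' @param label_flip_rate Probability that the signal class differs from the
#'   label.
#' @param seed Seed; deterministic given the spec.
#' @return A tibble (`id`, `label`, `probs` list-column of M-by-K matrices).
#' @examples
#' tr <- generate_trajectories(n_samples = 5, n_layers = 6, seed = 1)
#' normalized_entropy(tr$probs[[1]])
#' @export
generate_trajectories <- function(n_samples = 1000L, n_layers = 12L,
                                  n_classes = 4L, convergence_rate = 0.5,
                                  noise_scale = 0.5, label_flip_rate = 0.05,
                                  seed = 1L) {
  n_samples <- check_count(n_samples, "n_samples")
  n_layers <- check_count(n_layers, "n_layers")
  n_classes <- check_count(n_classes, "n_classes", min = 2L)
  label_flip_rate <- check_fraction(label_flip_rate, "label_flip_rate")
  seed <- check_count(seed, "seed", min = 0L)
  if (convergence_rate < 0 || noise_scale < 0) {
    abort("`convergence_rate` and `noise_scale` must be non-negative.",
          class = "epee_error_config")
  }
  withr::with_seed(seed, {
    labels <- sample.int(n_classes, n_samples, replace = TRUE)
    probs <- purrr::map(seq_len(n_samples), function(i) {
      signal <- labels[i]
      if (label_flip_rate > 0 && stats::runif(1) < label_flip_rate) {
        signal <- sample(setdiff(seq_len(n_classes), labels[i]), 1L)
      }
      z <- matrix(stats::rnorm(n_layers * n_classes, sd = noise_scale),
                  n_layers, n_classes)
      z[, signal] <- z[, signal] + convergence_rate * seq_len(n_layers)
      softmax_rows(z)
    })
    tibble::tibble(id = seq_len(n_samples), label = as.integer(labels),
                   probs = probs)
  })
}
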