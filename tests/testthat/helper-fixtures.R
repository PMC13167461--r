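# Shared fixtures: random trajectory builders and memoised trained models.

# A random but valid M x K probability trajectory (rows sum to 1).
random_trajectory <- function(M, K) {
  z <- matrix(rnorm(M * K), M, K)
  epee:::softmax_rows(z)
}

# Probability vector over K classes with a given winner and margin.
peaked_vector <- function(K, winner, strength) {
  z <- rep(0, K)
  z[winner] <- strength
  epee:::softmax_vec(z)
}

tiny_model_config <- function() {
  multi_exit_config(n_layers = 3L, hidden_size = 16L, n_heads = 2L,
                    ffn_size = 32L, vocab_size = 32L, max_positions = 12L,
                    n_classes = 3L)
}

# Study-scale corpus and trained models, built once per test run.  The
# corpus is the generator's default condition (N = 2000, K = 4); 1500
# records train, 500 are held out.
.fixture_env <- new.env(parent = emptyenv())

study_corpus <- function() {
  if (is.null(.fixture_env$corpus)) {
    .fixture_env$corpus <- generate_corpus(n_samples = 2000L, seed = 20260901L)
  }
  .fixture_env$corpus
}

study_split <- function() {
  corpus <- study_corpus()
  list(train = corpus[1:1500, ], test = corpus[1501:2000, ])
}

trained_study_model <- function(seed) {
  key <- paste0("fit_", seed)
  if (is.null(.fixture_env[[key]])) {
    sp <- study_split()
    model <- build_model(multi_exit_config(), seed = seed)
    .fixture_env[[key]] <- train_multi_exit(model, sp$train, epochs = 8L,
                                            seed = seed)
  }
  .fixture_env[[key]]
}
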