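test_that("published base geometries count to the expected parameter totals", {
  enc <- config_encoder_base()
  dec <- config_decoder_base()
  # independent shape enumeration of the encoder geometry
  d <- 768; f <- 3072
  enc_expected <- 30522 * d + 512 * d + 2 * d + 2 * d +     # embeddings + LN
    12 * (4 * (d * d + d) + 2 * d + (d * f + f) + (f * d + d) + 2 * d) +
    (d * d + d)                                             # pooler
  dec_expected <- 50257 * d + 1024 * d +
    12 * (4 * (d * d + d) + 2 * d + (d * f + f) + (f * d + d) + 2 * d) +
    2 * d                                                   # final LN
  expect_identical(count_parameters(enc), enc_expected)
  expect_identical(count_parameters(dec), dec_expected)
  expect_identical(floor(count_parameters(enc) / 1e6), 109)
  expect_identical(floor(count_parameters(dec) / 1e6), 124)
})

test_that("closed-form count matches a by-hand enumeration of a toy geometry", {
  cfg <- multi_exit_config(n_layers = 1, hidden_size = 2, n_heads = 1,
                           ffn_size = 2, vocab_size = 3, max_positions = 2,
                           n_token_types = 0, n_classes = 2,
                           include_pooler = FALSE, embed_layernorm = TRUE,
                           final_layernorm = FALSE)
  # tok 3x2 + pos 2x2 + embed LN 2+2
  # one layer: 4 x (2x2 + 2) attention, LN 2+2, FFN 2x2+2 and 2x2+2, LN 2+2
  by_hand <- (6 + 4 + 4) + (24 + 4 + 6 + 6 + 4)
  expect_identical(count_parameters(cfg), as.numeric(by_hand))
})

test_that("closed-form count equals the instantiated model's tally", {
  set.seed(5)
  for (i in 1:6) {
    heads <- sample(1:4, 1)
    cfg <- multi_exit_config(
      n_layers = sample(1:4, 1), hidden_size = heads * sample(2:6, 1) * 2,
      n_heads = heads, ffn_size = sample(4:20, 1),
      vocab_size = sample(5:40, 1), max_positions = sample(4:16, 1),
      n_token_types = sample(0:2, 1), n_classes = sample(2:6, 1),
      include_pooler = runif(1) < 0.5, embed_layernorm = runif(1) < 0.5,
      final_layernorm = runif(1) < 0.5
    )
    model <- build_model(cfg, seed = i)
    expect_identical(count_parameters(model), count_parameters(cfg))
  }
})

test_that("exit-head overhead matches its closed form and the printed bound", {
  enc9 <- config_encoder_base(n_classes_at = 9L)
  expect_identical(exit_head_params(enc9), 83052)
  expect_equal(exit_head_overhead(enc9), 100 * 83052 / (109482240 + 83052))
  expect_lt(exit_head_overhead(enc9), 3)
  # overhead strictly increases with the number of classes
  ov <- vapply(2:12, function(k) exit_head_overhead(config_encoder_base(k)),
               numeric(1))
  expect_true(all(diff(ov) > 0))
  # formula check on a minimal geometry
  small <- multi_exit_config(n_layers = 1, hidden_size = 2, n_heads = 1,
                             ffn_size = 2, vocab_size = 3, max_positions = 2,
                             n_classes = 2)
  expect_identical(exit_head_params(small), as.numeric(1 * (2 * 2 + 2)))
})

test_that("invalid geometries are rejected", {
  expect_error(multi_exit_config(hidden_size = 10, n_heads = 4),
               class = "epee_error_config")
  expect_error(multi_exit_config(n_classes = 1), class = "epee_error_config")
})

test_that("model initialization is deterministic under the seed", {
  cfg <- tiny_model_config()
  m1 <- build_model(cfg, seed = 9)
  m2 <- build_model(cfg, seed = 9)
  m3 <- build_model(cfg, seed = 10)
  expect_identical(m1$par, m2$par)
  expect_false(identical(m1$par, m3$par))
  expect_length(m1$par$heads, cfg$n_layers)
})

test_that("forward_all_exits emits one valid probability vector per layer", {
  cfg <- tiny_model_config()
  model <- build_model(cfg, seed = 2)
  set.seed(2)
  for (i in 1:5) {
    tk <- sample.int(cfg$vocab_size, sample(3:12, 1))
    P <- forward_all_exits(model, tk)
    expect_identical(dim(P), c(cfg$n_layers, cfg$n_classes))
    expect_true(all(abs(rowSums(P) - 1) < 1e-6))
    expect_identical(P, forward_all_exits(model, tk)) # deterministic
  }
  expect_error(forward_all_exits(model, c(1L, 999L)), class = "epee_error_input")
  expect_error(forward_all_exits(model, integer(0)), class = "epee_error_input")
})

test_that("forward_until_exit truncates computation at the exit layer", {
  cfg <- tiny_model_config()
  model <- build_model(cfg, seed = 4)
  set.seed(4)
  for (i in 1:10) {
    tk <- sample.int(cfg$vocab_size, 8)
    pc <- policy_config("epee", tau = runif(1), patience = sample.int(3, 1))
    reset_layer_calls(model)
    res <- forward_until_exit(model, tk, pc)
    expect_identical(layer_calls(model), res$trace$exit_layer)
  }
})

test_that("truncated and full forward passes give identical traces", {
  cfg <- tiny_model_config()
  model <- build_model(cfg, seed = 8)
  set.seed(8)
  for (i in 1:10) {
    tk <- sample.int(cfg$vocab_size, 10)
    pc <- policy_config("epee", tau = runif(1), patience = sample.int(3, 1))
    expect_identical(forward_until_exit(model, tk, pc)$trace,
                     run_policy(forward_all_exits(model, tk), pc))
  }
})

test_that("tau = 0 with patience = M degenerates to full-depth inference", {
  cfg <- tiny_model_config()
  model <- build_model(cfg, seed = 6)
  pc <- policy_config("epee", tau = 0, patience = cfg$n_layers)
  set.seed(6)
  for (i in 1:5) {
    tk <- sample.int(cfg$vocab_size, 6)
    reset_layer_calls(model)
    res <- forward_until_exit(model, tk, pc)
    expect_identical(layer_calls(model), cfg$n_layers)
    expect_identical(res$predicted_class,
                     argmax_class(forward_all_exits(model, tk)[cfg$n_layers, ]))
  }
})
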