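test_that("normalized entropy hits its closed-form anchor points", {
  expect_equal(normalized_entropy(rep(0.25, 4)), 1)
  expect_equal(normalized_entropy(c(1, 0, 0)), 0)
  expect_equal(normalized_entropy(c(0, 1)), 0)
  # two equal halves over four classes: log 2 / log 4
  expect_equal(normalized_entropy(c(0.5, 0.5, 0, 0)), 0.5)
  expect_equal(normalized_entropy(c(0.25, 0.25, 0.25, 0.25, 0, 0, 0, 0)),
               log(4) / log(8))
})

test_that("normalized entropy is in [0,1], 1 only at uniform, 0 only at one-hot", {
  set.seed(101)
  for (i in 1:200) {
    K <- sample(2:9, 1)
    p <- random_trajectory(1, K)[1, ]
    h <- normalized_entropy(p)
    expect_gte(h, 0)
    expect_lte(h, 1)
    if (max(abs(p - 1 / K)) > 1e-9) expect_lt(h, 1)
    if (sum(p > 1e-12) > 1L) expect_gt(h, 0)
  }
})

test_that("invalid distributions are rejected", {
  expect_error(normalized_entropy(c(1)), class = "epee_error_class_space")
  expect_error(normalized_entropy(c(0.5, 0.6)), class = "epee_error_distribution")
  expect_error(normalized_entropy(c(-0.1, 1.1)), class = "epee_error_distribution")
})

test_that("argmax breaks ties to the lowest class index", {
  expect_identical(argmax_class(c(0.1, 0.7, 0.2)), 2L)
  expect_identical(argmax_class(c(0.4, 0.4, 0.2)), 1L)
  expect_identical(argmax_class(rep(0.25, 4)), 1L)
  expect_error(argmax_class(numeric(0)), class = "epee_error_distribution")
})

test_that("patience counter increments on agreement and resets to 1 otherwise", {
  s <- list(count = 1L, last_class = 2L)
  expect_identical(update_patience(s, 2L)$count, 2L)
  s <- list(count = 3L, last_class = 1L)
  s2 <- update_patience(s, 2L)
  expect_identical(s2$count, 1L)
  expect_identical(s2$last_class, 2L)
  # a first observation is a run of length 1
  expect_identical(update_patience(patience_state(), 5L)$count, 1L)
})

test_that("per-layer decision honours both criteria and the final layer", {
  cfg <- policy_config("epee", tau = 0.2, patience = 3)
  expect_identical(decide_exit(0.05, 1L, 2L, cfg, 12L), "exit")     # entropy
  expect_identical(decide_exit(0.9, 3L, 5L, cfg, 12L), "exit")      # patience
  expect_identical(decide_exit(0.9, 2L, 5L, cfg, 12L), "continue")  # neither
  expect_identical(decide_exit(0.9, 1L, 12L, cfg, 12L), "exit")     # final
  expect_error(decide_exit(0.5, 1L, 13L, cfg, 12L), class = "epee_error_layer")
})

test_that("run_policy walks hand-simulated trajectories correctly", {
  # constant argmax, tau = 0: patience alone exits at layer P_t
  const <- do.call(rbind, replicate(6, peaked_vector(3, 1, 1), simplify = FALSE))
  tr <- run_policy(const, policy_config("epee", tau = 0, patience = 2))
  expect_identical(tr$exit_layer, 2L)
  expect_identical(tr$trigger, "patience")
  expect_identical(tr$patience_counts, c(1L, 2L))

  # neither criterion fires until layer 5, where both do
  probs <- rbind(c(0.20, 0.30, 0.50),
                 c(0.25, 0.30, 0.45),
                 c(0.40, 0.35, 0.25),
                 c(0.50, 0.30, 0.20),
                 c(0.96, 0.02, 0.02))
  tr <- run_policy(probs, policy_config("epee", tau = 0.25, patience = 3))
  expect_identical(tr$exit_layer, 5L)
  expect_identical(tr$predicted_class, 1L)
  expect_identical(tr$trigger, "both")
  expect_identical(tr$patience_counts, c(1L, 2L, 1L, 2L, 3L))
  expect_length(tr$entropies, 5L)

  # tau = 1: any non-uniform first layer exits immediately
  tr <- run_policy(probs, policy_config("epee", tau = 1, patience = 3))
  expect_identical(tr$exit_layer, 1L)
  expect_identical(tr$trigger, "entropy")

  # a final-layer emission with no criterion fired is flagged as such
  alt <- rbind(peaked_vector(3, 1, 1), peaked_vector(3, 2, 1),
               peaked_vector(3, 1, 1))
  tr <- run_policy(alt, policy_config("epee", tau = 0, patience = 2))
  expect_identical(tr$exit_layer, 3L)
  expect_identical(tr$trigger, "final_layer")
})

test_that("trace invariants hold on random inputs", {
  set.seed(7)
  for (i in 1:100) {
    M <- sample(2:12, 1); K <- sample(2:9, 1)
    probs <- random_trajectory(M, K)
    cfg <- policy_config("epee", tau = runif(1), patience = sample.int(M, 1))
    tr <- run_policy(probs, cfg)
    expect_length(tr$entropies, tr$exit_layer)
    expect_length(tr$patience_counts, tr$exit_layer)
    expect_true(all(tr$patience_counts >= 1L))
    expect_true(all(tr$patience_counts <= seq_len(tr$exit_layer)))
    if (tr$trigger == "final_layer") expect_identical(tr$exit_layer, M)
  }
})

test_that("run_policy agrees with the brute-force oracle on random instances", {
  set.seed(31)
  for (i in 1:500) {
    M <- sample(2:12, 1); K <- sample(2:9, 1)
    probs <- random_trajectory(M, K)
    cfg <- policy_config("epee", tau = runif(1), patience = sample.int(M, 1))
    expect_identical(run_policy(probs, cfg)$exit_layer,
                     exit_layer_oracle(probs, cfg))
  }
})

test_that("hybrid exit is the min of the entropy-only and patience-only exits", {
  set.seed(53)
  for (i in 1:200) {
    M <- sample(2:12, 1); K <- sample(2:6, 1)
    probs <- random_trajectory(M, K)
    tau <- runif(1); pt <- sample.int(M, 1)
    e_epee <- run_policy(probs, policy_config("epee", tau = tau, patience = pt))$exit_layer
    e_ent <- run_policy(probs, policy_config("entropy", tau = tau))$exit_layer
    e_pat <- run_policy(probs, policy_config("patience", patience = pt))$exit_layer
    expect_identical(e_epee, min(e_ent, e_pat))
  }
})

test_that("exit layer is monotone in tau and in patience", {
  set.seed(67)
  taus <- c(0, 0.1, 0.3, 0.6, 1)
  for (i in 1:50) {
    M <- 8L; K <- 4L
    probs <- random_trajectory(M, K)
    pt <- sample.int(M, 1)
    exits_tau <- vapply(taus, function(tau) {
      run_policy(probs, policy_config("epee", tau = tau, patience = pt))$exit_layer
    }, integer(1))
    expect_true(all(diff(exits_tau) <= 0))  # non-increasing in tau
    tau <- runif(1)
    exits_pt <- vapply(seq_len(M), function(p) {
      run_policy(probs, policy_config("epee", tau = tau, patience = p))$exit_layer
    }, integer(1))
    expect_true(all(diff(exits_pt) >= 0))   # non-decreasing in patience
  }
})

test_that("degenerate settings reproduce the single-criterion policies", {
  set.seed(71)
  for (i in 1:100) {
    M <- sample(2:12, 1); K <- sample(2:6, 1)
    probs <- random_trajectory(M, K)
    pt <- sample.int(M, 1); tau <- runif(1)
    expect_identical(run_policy(probs, policy_config("epee", tau = 0, patience = pt)),
                     run_policy(probs, policy_config("patience", patience = pt)))
    expect_identical(run_policy(probs, policy_config("epee", tau = tau, patience = M)),
                     run_policy(probs, policy_config("entropy", tau = tau)))
  }
  # tau = 0 never fires even for one-hot predictions (strict inequality)
  onehot <- diag(3)[c(1, 1, 1), ]
  tr <- run_policy(onehot, policy_config("epee", tau = 0, patience = 3))
  expect_identical(tr$exit_layer, 3L)
  expect_identical(tr$trigger, "patience")
})

test_that("patience threshold 1 forces exit at the first layer", {
  set.seed(79)
  probs <- random_trajectory(6, 4)
  tr <- run_policy(probs, policy_config("epee", tau = 0, patience = 1))
  expect_identical(tr$exit_layer, 1L)
})

test_that("run_policy_all unpacks traces into one tidy row per sample", {
  tr <- generate_trajectories(n_samples = 25, n_layers = 6, seed = 3)
  out <- run_policy_all(tr, policy_config("epee", tau = 0.3, patience = 2))
  expect_identical(nrow(out), 25L)
  expect_true(all(c("id", "label", "exit_layer", "predicted_class",
                    "trigger", "entropies", "patience_counts") %in% names(out)))
  expect_true(all(lengths(out$entropies) == out$exit_layer))
})
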