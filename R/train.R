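#' Per-exit loss weights
#'
#' Weights for the joint training objective, a weighted average of the
#' per-exit cross-entropies.  The default `"linear_cost"` scheme sets
#' \eqn{w_m = m}: the relative inference cost of reaching exit m is
#' proportional to the m layers executed.  `"uniform"` weights every exit
#' equally (retained as an ablation switch).
#'
#' @param n_layers Number of exits M.
#' @param scheme `"linear_cost"` or `"uniform"`.
#' @return A positive numeric vector of length `n_layers`.
#' @export
loss_weights <- function(n_layers, scheme = c("linear_cost", "uniform")) {
  scheme <- match.arg(scheme)
  n_layers <- check_count(n_layers, "n_layers")
  switch(scheme,
         linear_cost = as.numeric(seq_len(n_layers)),
         uniform = rep(1, n_layers))
}

#' Joint multi-exit loss for one sample
#'
#' The layer-cost-weighted average of per-exit cross-entropies,
#' \eqn{\sum_m w_m CE_m / \sum_m w_m} with
#' \eqn{CE_m = -\log p_m[\mathrm{label}]}.  Predicted probabilities are
#' floored at 1e-12 before the logarithm so a confidently wrong head yields
#' a large finite loss rather than an infinity.
#'
#' @param probs An M-by-K matrix of per-exit class probabilities.
#' @param label True class index (1-based).
#' @param weights Positive per-exit weights of length M; see
#'   [loss_weights()].
#' @return A non-negative number.
#' @examples
#' p <- rbind(c(0.7, 0.3), c(0.9, 0.1))
#' joint_loss(p, 1L, loss_weights(2, "uniform"))
#' @export
joint_loss <- function(probs, label, weights) {
  check_prob_matrix(probs)
  label <- check_count(label, "label")
  if (label > ncol(probs)) {
    abort("`label` exceeds the number of classes.", class = "epee_error_config")
  }
  if (length(weights) != nrow(probs)) {
    abort("`weights` must have one entry per exit.", class = "epee_error_config")
  }
  if (any(weights <= 0)) {
    abort("`weights` must be positive.", class = "epee_error_config")
  }
  ce <- -log(pmax(probs[, label], 1e-12))
  sum(weights * ce) / sum(weights)
}

flatten_params <- function(p, prefix = character()) {
  if (is.list(p)) {
    out <- list()
    for (nm in names(p)) {
      if (is.null(p[[nm]])) next
      out <- c(out, flatten_params(p[[nm]], c(prefix, nm)))
    }
    # unnamed lists (layers, heads)
    if (is.null(names(p))) {
      for (i in seq_along(p)) {
        out <- c(out, flatten_params(p[[i]], c(prefix, as.character(i))))
      }
    }
    out
  } else {
    stats::setNames(list(p), paste(prefix, collapse = "."))
  }
}

assign_path <- function(p, path, value) {
  key <- path[[1L]]
  idx <- if (grepl("^[0-9]+$", key)) as.integer(key) else key
  if (length(path) == 1L) {
    p[[idx]] <- value
  } else {
    p[[idx]] <- assign_path(p[[idx]], path[-1L], value)
  }
  p
}

unflatten_into <- function(par, flat) {
  for (nm in names(flat)) {
    par <- assign_path(par, strsplit(nm, ".", fixed = TRUE)[[1L]], flat[[nm]])
  }
  par
}

#' Jointly train backbone and all exit heads
#'
#' Optimizes every parameter (backbone plus all M heads) with Adam against
#' the weighted multi-exit cross-entropy of [joint_loss()], computed over
#' mini-batches with hand-derived analytic gradients.  Training is
#' deterministic given `seed` (which drives shuffling; the model's own
#' initialization seed was fixed at [build_model()] time).  Stops early when
#' the epoch loss plateaus.
#'
#' @param model An untrained (or previously trained) `multi_exit_model`.
#' @param corpus A tibble with list-column `tokens` (equal-length integer
#'   sequences) and column `label`.
#' @param epochs Maximum number of epochs.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param weights Per-exit loss weights; default [loss_weights()] with the
#'   `"linear_cost"` scheme.
#' @param seed Seed for batch shuffling.
#' @param early_stop_tol Relative epoch-loss improvement below which an
#'   epoch counts as a plateau.
#' @param early_stop_patience Consecutive plateau epochs tolerated before
#'   stopping.
#' @param verbose Print per-epoch loss.
#' @return The trained model, with a `history` tibble (`epoch`, `mean_loss`,
#'   list-column `exit_accuracy` of per-exit training accuracies, and
#'   `early_stopped`).
#' @export
train_multi_exit <- function(model, corpus, epochs = 8L, batch_size = 32L,
                             learning_rate = 1e-3, weights = NULL,
                             seed = 1L, early_stop_tol = 1e-3,
                             early_stop_patience = 2L, verbose = FALSE) {
  stopifnot(inherits(model, "multi_exit_model"))
  if (!is.data.frame(corpus) || nrow(corpus) == 0L) {
    abort("`corpus` must be a non-empty data frame.", class = "epee_error_data")
  }
  cfg <- model$config
  labels_all <- as.integer(corpus$label)
  if (any(labels_all < 1L) || any(labels_all > cfg$n_classes)) {
    abort("labels must lie in [1, n_classes].", class = "epee_error_data")
  }
  lens <- lengths(corpus$tokens)
  if (length(unique(lens)) != 1L) {
    abort("all token sequences must share one length for batched training.",
          class = "epee_error_data")
  }
  Tn <- lens[[1L]]
  ids_all <- do.call(rbind, lapply(corpus$tokens, as.integer))
  w <- weights %||% loss_weights(cfg$n_layers, "linear_cost")
  if (length(w) != cfg$n_layers || any(w <= 0)) {
    abort("`weights` must be positive and of length n_layers.",
          class = "epee_error_config")
  }

  par <- model$par
  flat <- flatten_params(par)
  mstate <- purrr::map(flat, function(p) p * 0)
  vstate <- mstate
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  N <- nrow(ids_all)
  M <- cfg$n_layers

  history <- vector("list", epochs)
  plateau <- 0L
  prev_loss <- Inf
  stopped <- FALSE

  withr::with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      ep_loss <- 0
      n_batches <- 0L
      correct <- integer(M)
      for (start in seq(1L, N, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, N)]
        ids <- ids_all[idx, , drop = FALSE]
        labs <- labels_all[idx]
        fw <- batched_forward(par, cfg, ids)
        bw <- batched_backward(par, cfg, fw, labs, w)
        for (m in seq_len(M)) {
          correct[m] <- correct[m] +
            sum(max.col(fw$probs[[m]], ties.method = "first") == labs)
        }
        step <- step + 1L
        gflat <- flatten_params(bw$grads)
        for (nm in names(flat)) {
          gv <- gflat[[nm]]
          mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * gv
          vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * gv^2
          mhat <- mstate[[nm]] / (1 - beta1^step)
          vhat <- vstate[[nm]] / (1 - beta2^step)
          flat[[nm]] <- flat[[nm]] - learning_rate * mhat / (sqrt(vhat) + eps)
        }
        par <- unflatten_into(par, flat)
        ep_loss <- ep_loss + bw$loss * length(idx)
        n_batches <- n_batches + 1L
      }
      ep_loss <- ep_loss / N
      history[[ep]] <- tibble::tibble(
        epoch = ep, mean_loss = ep_loss,
        exit_accuracy = list(correct / N),
        early_stopped = FALSE
      )
      if (verbose) message(sprintf("epoch %d: loss %.4f", ep, ep_loss))
      rel_impr <- (prev_loss - ep_loss) / max(abs(prev_loss), 1e-12)
      plateau <- if (is.finite(rel_impr) && rel_impr < early_stop_tol) {
        plateau + 1L
      } else 0L
      prev_loss <- ep_loss
      if (plateau >= early_stop_patience && ep < epochs) {
        stopped <- TRUE
        break
      }
    }
  })

  hist_tbl <- dplyr::bind_rows(history[!vapply(history, is.null, logical(1))])
  if (stopped) hist_tbl$early_stopped[nrow(hist_tbl)] <- TRUE
  out <- model
  out$par <- par
  out$history <- hist_tbl
  out$train_seed <- seed
  out
}
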