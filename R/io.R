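# JSONL serialization for corpora, trajectories and traces, plus model
# checkpoints and run manifests.

write_jsonl <- function(rows, path) {
  lines <- vapply(rows, function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

read_jsonl <- function(path) {
  lapply(readLines(path), jsonlite::fromJSON, simplifyVector = TRUE)
}

#' Read and write corpora, trajectories and traces as JSONL
#'
#' One JSON object per line.  Corpus records carry `id`, `tokens`, `label`,
#' `difficulty`; trajectory records carry `id`, `label` and `probs` (a
#' layers-by-classes array); trace records carry `id`, `pred`, `exit_layer`,
#' `trigger`.  Class and token indices are 1-based, as everywhere in the
#' package.
#'
#' @param corpus,data A tibble as produced by [generate_corpus()],
#'   [generate_trajectories()] / [collect_trajectories()], or
#'   [run_policy_all()] respectively.
#' @param path File path.
#' @return Readers return a tibble; writers return `path` invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  rows <- purrr::pmap(corpus[c("id", "tokens", "label", "difficulty")],
                      function(id, tokens, label, difficulty) {
                        list(id = id, tokens = tokens, label = label,
                             difficulty = difficulty)
                      })
  write_jsonl(rows, path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  rows <- read_jsonl(path)
  tibble::tibble(
    id = purrr::map_int(rows, function(r) as.integer(r$id)),
    tokens = purrr::map(rows, function(r) as.integer(r$tokens)),
    label = purrr::map_int(rows, function(r) as.integer(r$label)),
    difficulty = purrr::map_chr(rows, "difficulty")
  )
}

#' @rdname write_corpus_jsonl
#' @export
write_trajectories_jsonl <- function(data, path) {
  rows <- purrr::pmap(data[c("id", "label", "probs")],
                      function(id, label, probs) {
                        list(id = id, label = label, probs = probs)
                      })
  write_jsonl(rows, path)
}

#' @rdname write_corpus_jsonl
#' @export
read_trajectories_jsonl <- function(path) {
  rows <- read_jsonl(path)
  tibble::tibble(
    id = purrr::map_int(rows, function(r) as.integer(r$id)),
    label = purrr::map_int(rows, function(r) as.integer(r$label)),
    probs = purrr::map(rows, function(r) {
      m <- r$probs
      if (!is.matrix(m)) m <- matrix(m, nrow = 1L)
      m
    })
  )
}

#' @rdname write_corpus_jsonl
#' @export
write_traces_jsonl <- function(data, path) {
  rows <- purrr::pmap(data[c("id", "predicted_class", "exit_layer", "trigger")],
                      function(id, predicted_class, exit_layer, trigger) {
                        list(id = id, pred = predicted_class,
                             exit_layer = exit_layer, trigger = trigger)
                      })
  write_jsonl(rows, path)
}

#' Save and load model checkpoints
#'
#' A checkpoint stores a format version, the geometry, all parameters, the
#' training history and the seeds, so one trained model can be reloaded and
#' reused across every exit strategy.
#'
#' @param model A `multi_exit_model`.
#' @param path Checkpoint file path.
#' @return `load_checkpoint()` returns the restored model (with a fresh
#'   layer-call counter).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "multi_exit_model"))
  saveRDS(list(version = 1L, config = model$config, par = model$par,
               history = model$history, seed = model$seed,
               train_seed = model$train_seed), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, 1L)) {
    abort("unsupported checkpoint version.", class = "epee_error_io")
  }
  structure(
    list(config = obj$config, par = obj$par, seed = obj$seed,
         counter = new.env(parent = emptyenv()), history = obj$history,
         train_seed = obj$train_seed),
    class = "multi_exit_model"
  )
}

#' Write a run manifest
#'
#' Records the seed, the echoed generation/run spec and a hash of it next to
#' every output artifact, so identical spec + seed reproduces identical
#' files.
#'
#' @param path Manifest file path (JSON).
#' @param seed The seed used.
#' @param spec A named list echoing the parameters of the run.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, seed, spec) {
  jsonlite::write_json(
    list(seed = seed, spec = spec, config_hash = rlang::hash(spec)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
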