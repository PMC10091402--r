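# Sequence-to-sequence translation harness: train an encoder-decoder
# transformer on tokenized reaction task samples, decode n-best candidate
# lists with beam search, and adapt a trained model as a forward-model
# contract for round-trip evaluation.

#' Translator model configuration
#'
#' Two presets: `"paper"` is the full-scale molecular-transformer shape
#' (4 layers, embedding 256, feed-forward 2048, 8 heads, 4096-token
#' batches, validation every 10000 steps times the augmentation factor);
#' `"desk"` is a reduced shape (2 layers, embedding 64, feed-forward 256,
#' 4 heads) that trains a small task on one CPU in minutes. Both decode
#' with beam size 10 and stop early when neither validation token accuracy
#' nor perplexity has improved for `patience` consecutive validations.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param augmentation_factor scales `validate_every`, so one "validation
#'   epoch" covers a comparable share of the (augmented) training set.
#' @param freeze_input_embeddings replace the input embedding layer by a
#'   pre-trained [train_embeddings()] table and keep it fixed during
#'   training.
#' @param seed integer seed for initialization, batching and shuffling.
#' @param ... overrides for any field (`n_layers`, `d_model`, `ff_dim`,
#'   `n_heads`, `batch_tokens`, `beam_size`, `patience`, `validate_every`,
#'   `max_steps`, `lr`, `grad_clip`, `max_decode_len`).
#' @return a list of class `rxn_model_config`.
#' @export
model_config <- function(preset = c("desk", "paper"), augmentation_factor = 1L,
                         freeze_input_embeddings = FALSE, seed = 0L, ...) {
  preset <- match.arg(preset)
  base <- if (preset == "paper") {
    list(n_layers = 4L, d_model = 256L, ff_dim = 2048L, n_heads = 8L,
         batch_tokens = 4096L, beam_size = 10L, patience = 10L,
         validate_every = 10000L, max_steps = 500000L, lr = 5e-4,
         grad_clip = 1, max_decode_len = 200L)
  } else {
    list(n_layers = 2L, d_model = 64L, ff_dim = 256L, n_heads = 4L,
         batch_tokens = 1024L, beam_size = 10L, patience = 10L,
         validate_every = 200L, max_steps = 4000L, lr = 1e-3,
         grad_clip = 1, max_decode_len = 120L)
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(base))
  if (length(unknown) > 0L)
    abort_config(paste("unknown model_config fields:", paste(unknown, collapse = ", ")))
  base[names(dots)] <- dots
  base$validate_every <- as.integer(base$validate_every * augmentation_factor)
  base$freeze_input_embeddings <- freeze_input_embeddings
  base$seed <- as.integer(seed)
  base$preset <- preset
  if (base$beam_size < 1L || base$patience < 1L)
    abort_config("beam_size and patience must be >= 1")
  structure(base, class = "rxn_model_config")
}

cpp_config <- function(config, vocab_size, tok) {
  list(n_layers = config$n_layers, d_model = config$d_model,
       ff_dim = config$ff_dim, n_heads = config$n_heads,
       vocab = as.integer(vocab_size),
       batch_tokens = config$batch_tokens, beam_size = config$beam_size,
       patience = config$patience, validate_every = config$validate_every,
       max_steps = config$max_steps,
       bos_id = match("<bos>", tok$vocab$tokens),
       eos_id = match("<eos>", tok$vocab$tokens),
       max_decode_len = config$max_decode_len,
       lr = config$lr, grad_clip = config$grad_clip,
       freeze_src_emb = isTRUE(config$freeze_input_embeddings),
       seed = config$seed)
}

#' Train a reaction translator
#'
#' Fits (if necessary) the tokenizer on the training strings, encodes all
#' samples, and trains the encoder-decoder transformer with token-budgeted
#' batches and early stopping: training stops when neither validation
#' token accuracy nor perplexity has improved within `patience` consecutive
#' validations, and the best validated parameters are retained.
#'
#' @param train_samples,valid_samples task-sample tibbles with `source` and
#'   `target` columns.
#' @param config an [model_config()].
#' @param tokenizer a [tokenizer_spec()] (fitted or not; fitted here on the
#'   training strings when not).
#' @param embeddings an `rxn_embedding_table`, required when
#'   `config$freeze_input_embeddings` is set; must cover every vocabulary
#'   token and match `d_model`.
#' @return an object of class `rxn_translator` with the trained parameters,
#'   the tokenizer, the configuration and the training log (per-validation
#'   token accuracy and perplexity, stopping step and reason).
#' @export
translator_train <- function(train_samples, valid_samples, config,
                             tokenizer = tokenizer_spec("atom", "smiles"),
                             embeddings = NULL) {
  stopifnot(inherits(config, "rxn_model_config"))
  if (nrow(train_samples) == 0L) abort_config("empty training set")
  if (is.null(tokenizer$vocab))
    tokenizer <- fit_tokenizer(tokenizer, c(train_samples$source, train_samples$target))
  vocab_size <- length(tokenizer$vocab$tokens)

  if (isTRUE(config$freeze_input_embeddings)) {
    if (is.null(embeddings))
      abort_config("freeze_input_embeddings requires an embedding table")
    missing <- setdiff(tokenizer$vocab$tokens, rownames(embeddings$vectors))
    if (length(missing) > 0L)
      abort_rxn(paste("embedding table does not cover vocabulary tokens:",
                      paste(utils::head(missing, 5), collapse = " ")),
                class = "rxn_coverage_error")
    if (embeddings$dim != config$d_model)
      abort_config("embedding dimension must equal d_model for the frozen layer")
  }

  enc <- function(samples) {
    list(src = lapply(samples$source, function(s) as.integer(encode_string(tokenizer, s))),
         tgt = lapply(samples$target, function(s) as.integer(encode_string(tokenizer, s))))
  }
  tr <- enc(train_samples); va <- enc(valid_samples)
  cfg <- cpp_config(config, vocab_size, tokenizer)
  params <- tf_init(cfg)
  if (isTRUE(config$freeze_input_embeddings))
    params$src_emb <- unname(embeddings$vectors[tokenizer$vocab$tokens, , drop = FALSE])
  fit <- tf_train(params, cfg, tr$src, tr$tgt, va$src, va$tgt)
  structure(
    list(params = fit$params, config = config, tokenizer = tokenizer,
         log = tibble::as_tibble(fit$log),
         stopped_at = fit$stopped_at, best_step = fit$best_step,
         stop_reason = fit$stop_reason),
    class = "rxn_translator"
  )
}

#' @export
print.rxn_translator <- function(x, ...) {
  cat(sprintf(
    "<rxn_translator: %s preset, %d-token vocabulary, stopped at step %d (%s), best step %d>\n",
    x$config$preset, length(x$tokenizer$vocab$tokens), x$stopped_at,
    x$stop_reason, x$best_step))
  invisible(x)
}

#' Beam-search n-best prediction
#'
#' Decodes each source with beam search (beam size from the model
#' configuration) and returns the `k` best candidates per source with
#' their cumulative log-probabilities, non-increasing by rank. Inference
#' is deterministic for a fixed model. Candidate token sequences are
#' detokenized by concatenation; whether a candidate parses as chemistry
#' is left to the evaluation layer.
#'
#' @param object a trained `rxn_translator`.
#' @param sources character vector of source strings.
#' @param k number of candidates per source; must not exceed the beam size.
#' @param ... unused.
#' @return a list (one element per source) of tibbles with `rank`,
#'   `score`, `candidate`.
#' @export
predict.rxn_translator <- function(object, sources, k = 1L, ...) {
  if (k < 1L || k > object$config$beam_size)
    abort_rxn(sprintf("k = %d outside 1..beam_size (%d)", k, object$config$beam_size),
              class = "rxn_argument_error")
  tok <- object$tokenizer
  cfg <- cpp_config(object$config, length(tok$vocab$tokens), tok)
  src_ids <- lapply(sources, function(s) as.integer(encode_string(tok, s)))
  raw <- tf_predict(object$params, cfg, src_ids, as.integer(k))
  lapply(raw, function(r) {
    tibble::tibble(
      rank = seq_along(r$ids),
      score = as.numeric(r$scores),
      candidate = vapply(r$ids, function(ids) decode_ids(tok, ids), character(1))
    )
  })
}

#' Adapt a trained translator as a forward-model contract
#'
#' Wraps a product-prediction translator as the `function(source) ->
#' product` contract consumed by [roundtrip_accuracy()]. Use the matched
#' model: same augmentation factor and reagent setting as the reactant
#' model under evaluation.
#'
#' @param model a trained `rxn_translator` for the product task.
#' @return a function mapping a source string to the rank-1 predicted
#'   product string.
#' @export
translator_as_forward_model <- function(model) {
  function(source) predict(model, source, k = 1L)[[1]]$candidate[1]
}

#' Save a trained translator with a run manifest
#'
#' Writes the model checkpoint (`checkpoint.rds`) together with a
#' plain-text run manifest echoing the configuration, the vocabulary size
#' and the training outcome, so a run can be identified and reloaded later.
#'
#' @param model a trained `rxn_translator`.
#' @param dir directory to create/populate.
#' @return the manifest path, invisibly.
#' @export
save_translator <- function(model, dir) {
  stopifnot(inherits(model, "rxn_translator"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ckpt <- file.path(dir, "checkpoint.rds")
  saveRDS(model, ckpt)
  cfg <- model$config
  fields <- setdiff(names(cfg), "preset")
  manifest <- c(
    sprintf("checkpoint: %s", ckpt),
    sprintf("preset: %s", cfg$preset),
    vapply(fields, function(f) sprintf("%s: %s", f, format(cfg[[f]])), character(1)),
    sprintf("vocab_size: %d", length(model$tokenizer$vocab$tokens)),
    sprintf("tokenizer: %s/%s (%d merges)", model$tokenizer$scheme,
            model$tokenizer$dialect, length(model$tokenizer$merges)),
    sprintf("stopped_at: %d", model$stopped_at),
    sprintf("best_step: %d", model$best_step),
    sprintf("stop_reason: %s", model$stop_reason)
  )
  path <- file.path(dir, "manifest.txt")
  writeLines(manifest, path)
  invisible(path)
}

#' @rdname save_translator
#' @export
load_translator <- function(dir) {
  readRDS(file.path(dir, "checkpoint.rds"))
}

#' Assemble prediction records from samples and model output
#'
#' @param samples a task-sample tibble (with `reagents` and `products`
#'   metadata columns when available).
#' @param preds the list returned by [predict.rxn_translator()] for
#'   `samples$source`.
#' @param task,include_reagents metadata stored on each record.
#' @return a list of [prediction_record()] objects.
#' @export
predictions_to_records <- function(samples, preds, task = NA_character_,
                                   include_reagents = NA) {
  lapply(seq_len(nrow(samples)), function(i) {
    prediction_record(
      source = samples$source[i], target = samples$target[i],
      candidates = preds[[i]]$candidate, scores = preds[[i]]$score,
      task = task, include_reagents = include_reagents,
      true_reagents = if ("reagents" %in% names(samples)) samples$reagents[[i]],
      products = if ("products" %in% names(samples)) samples$products[[i]]
    )
  })
}
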