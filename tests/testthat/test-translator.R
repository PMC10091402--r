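# Translation harness: gradient correctness, training contracts,
# beam-search prediction contracts.

tiny_tokenizer <- function() {
  fit_tokenizer(tokenizer_spec("atom", "smiles"), c("CCO.CC", "CCN", "OCC", "CCS"))
}

test_that("analytic gradients match finite differences", {
  tok <- tiny_tokenizer()
  cfg <- rxnpredict:::cpp_config(
    model_config("desk", n_layers = 1, d_model = 8, ff_dim = 16, n_heads = 2,
                 seed = 3),
    length(tok$vocab$tokens), tok)
  params <- rxnpredict:::tf_init(cfg)
  src <- as.integer(encode_string(tok, "CCO.CC"))
  tgt <- as.integer(encode_string(tok, "CCN"))
  res <- rxnpredict:::tf_loss_grad(params, cfg, src, tgt)
  eps <- 1e-5
  set.seed(42)
  for (nm in sample(names(params), 8)) {
    i <- sample(length(params[[nm]]), 1)
    p2 <- params
    p2[[nm]][i] <- p2[[nm]][i] + eps
    up <- rxnpredict:::tf_loss_grad(p2, cfg, src, tgt)$loss
    p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
    dn <- rxnpredict:::tf_loss_grad(p2, cfg, src, tgt)$loss
    num <- (up - dn) / (2 * eps)
    expect_equal(res$grads[[nm]][i], num, tolerance = 1e-4)
  }
})

train_tiny <- function(freeze = FALSE, embeddings = NULL, seed = 0,
                       max_steps = 60) {
  mols <- fixture_generated_molecules(80, seed = 51)
  samples <- tibble::tibble(source = mols, target = mols)
  translator_train(samples[1:60, ], samples[61:80, ],
                   model_config("desk", n_layers = 1, d_model = 16, ff_dim = 32,
                                n_heads = 2, batch_tokens = 256,
                                validate_every = 20, max_steps = max_steps,
                                freeze_input_embeddings = freeze, seed = seed),
                   embeddings = embeddings)
}

test_that("training returns a usable handle with a validation log", {
  m <- train_tiny()
  expect_s3_class(m, "rxn_translator")
  expect_true(all(c("step", "token_accuracy", "perplexity") %in% names(m$log)))
  expect_true(all(m$log$token_accuracy >= 0 & m$log$token_accuracy <= 1))
  expect_true(all(m$log$perplexity >= 1))
  expect_true(m$stop_reason %in% c("early_stopping", "max_steps"))
  # the early-stopping invariant: the retained best step is one at which a
  # validation metric improved, never later than the stopping step
  expect_lte(m$best_step, m$stopped_at)
  preds <- predict(m, c("CCO", "CC"), k = 1)
  expect_length(preds, 2L)
  expect_identical(nrow(preds[[1]]), 1L)
})

test_that("training rejects degenerate inputs", {
  empty <- tibble::tibble(source = character(0), target = character(0))
  some <- tibble::tibble(source = "CCO", target = "CCO")
  expect_error(translator_train(empty, some, model_config("desk")),
               class = "rxn_config_error")
  expect_error(train_tiny(freeze = TRUE), class = "rxn_config_error")
})

test_that("frozen input embeddings are bit-identical after training", {
  mols <- fixture_generated_molecules(80, seed = 51)
  rec <- generate_reactions(synthetic_config(80, seed = 51))
  corpus <- build_molecule_corpus(rec, tokenizer_spec("atom", "smiles"))
  tab <- train_embeddings(corpus, dim = 16, seed = 1, epochs = 2)
  m <- train_tiny(freeze = TRUE, embeddings = tab, max_steps = 40)
  expected <- unname(tab$vectors[m$tokenizer$vocab$tokens, , drop = FALSE])
  expect_identical(max(abs(m$params$src_emb - expected)), 0)
})

test_that("a frozen run needs full vocabulary coverage", {
  corpus <- list(c("C", "C", "O"))  # misses most vocabulary tokens
  tab <- train_embeddings(corpus, dim = 16, seed = 1, epochs = 1)
  expect_error(train_tiny(freeze = TRUE, embeddings = tab),
               class = "rxn_coverage_error")
})

test_that("beam predictions are deterministic, ranked, and bounded by beam size", {
  m <- train_tiny()
  p1 <- predict(m, c("CCO", "CCOC"), k = 5)
  p2 <- predict(m, c("CCO", "CCOC"), k = 5)
  expect_identical(p1, p2)
  for (p in p1) {
    expect_lte(nrow(p), 5L)
    expect_true(all(diff(p$score) <= 1e-12))  # non-increasing by rank
  }
  expect_error(predict(m, "CCO", k = 11), class = "rxn_argument_error")
  expect_error(predict(m, "CCO", k = 0), class = "rxn_argument_error")
})

test_that("training is reproducible for a fixed seed", {
  a <- train_tiny(seed = 4, max_steps = 30)
  b <- train_tiny(seed = 4, max_steps = 30)
  expect_identical(a$params, b$params)
  expect_identical(a$log, b$log)
})
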