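# Atom-level and pair-encoding tokenization.

test_that("atom tokenization follows the molecular-transformer token rules", {
  expect_identical(atom_tokenize("CC(=O)O"),
                   c("C", "C", "(", "=", "O", ")", "O"))
  expect_identical(atom_tokenize("[nH]"), "[nH]")
  expect_identical(atom_tokenize("Cl"), "Cl")
  expect_identical(atom_tokenize("ClC(Cl)Cl"), c("Cl", "C", "(", "Cl", ")", "Cl"))
  expect_identical(atom_tokenize("C%12CC%12"), c("C", "%12", "C", "C", "%12"))
  expect_identical(atom_tokenize(""), character(0))
  expect_identical(atom_tokenize("CCO.CC"), c("C", "C", "O", ".", "C", "C"))
  expect_identical(atom_tokenize("[C][=O]", dialect = "selfies"),
                   c("[C]", "[=O]"))
})

test_that("token concatenation reconstructs the input for both dialects", {
  for (m in fixture_molecules()) {
    expect_identical(paste(atom_tokenize(m), collapse = ""), m)
    se <- to_selfies(m)
    expect_identical(paste(atom_tokenize(se, "selfies"), collapse = ""), se)
  }
})

test_that("dangling brackets raise a tokenization error", {
  expect_error(atom_tokenize("[nH"), class = "rxn_tokenization_error")
  expect_error(atom_tokenize("C[X"), class = "rxn_tokenization_error")
})

test_that("pair encoding merges frequent pairs and respects the threshold", {
  corpus <- c(rep("CCO", 60), rep("CCN", 50), rep("OCO", 10))
  toks <- lapply(corpus, atom_tokenize)
  # ("C","C") occurs 110 times; with threshold 100 only it merges
  fit <- train_bpe(toks, min_substring_freq = 100)
  expect_length(fit$merges, 1L)
  expect_identical(fit$merges[[1]], c("C", "C"))
  expect_identical(fit$corpus[[1]], c("CC", "O"))
  # threshold above every pair frequency: no merges at all
  none <- train_bpe(toks, min_substring_freq = 1000)
  expect_length(none$merges, 0L)
  expect_error(train_bpe(list(), 10), class = "rxn_config_error")
})

test_that("every merge's formation frequency meets the threshold", {
  mols <- fixture_generated_molecules(300)
  toks <- lapply(mols, atom_tokenize)
  thr <- 40L
  fit <- train_bpe(toks, min_substring_freq = thr)
  expect_gt(length(fit$merges), 0L)
  # replay the merges, counting each pair's frequency at formation time
  replay <- lapply(mols, atom_tokenize)
  for (ab in fit$merges) {
    key <- paste(ab[1], ab[2], sep = "\x1f")
    freq <- sum(vapply(replay, function(s) {
      if (length(s) < 2) return(0L)
      sum(s[-length(s)] == ab[1] & s[-1] == ab[2])
    }, integer(1)))
    expect_gte(freq, thr)
    replay <- lapply(replay, rxnpredict:::merge_pair_in_seq, a = ab[1], b = ab[2])
  }
})

test_that("merges never absorb the '.' separator or specials", {
  corpus <- lapply(rep("CCO.CCO", 100), atom_tokenize)
  fit <- train_bpe(corpus, min_substring_freq = 10)
  merged <- vapply(fit$merges, paste, character(1), collapse = "")
  expect_false(any(grepl(".", merged, fixed = TRUE)))
})

test_that("encode/decode round-trips and merges only shorten", {
  mols <- fixture_generated_molecules(150)
  atom_tok <- fit_tokenizer(tokenizer_spec("atom", "smiles"), mols)
  bpe_tok <- fit_tokenizer(tokenizer_spec("bpe", "smiles", min_substring_freq = 20), mols)
  expect_gt(length(bpe_tok$merges), 0L)
  for (m in mols[1:50]) {
    for (tok in list(atom_tok, bpe_tok)) {
      ids <- encode_string(tok, m)
      expect_identical(attr(ids, "n_unk"), 0L)
      expect_identical(decode_ids(tok, ids), m)
    }
    expect_gte(length(encode_string(atom_tok, m)),
               length(encode_string(bpe_tok, m)))
  }
  # pair-encoding vocabulary strictly contains the atom vocabulary
  expect_true(all(atom_tok$vocab$tokens %in% bpe_tok$vocab$tokens))
  expect_gt(length(bpe_tok$vocab$tokens), length(atom_tok$vocab$tokens))
})

test_that("out-of-vocabulary symbols map to <unk> and are flagged", {
  tok <- fit_tokenizer(tokenizer_spec("atom", "smiles"), c("CCO", "CCN"))
  ids <- encode_string(tok, "CCS")
  expect_identical(attr(ids, "n_unk"), 1L)
  expect_identical(tok$vocab$tokens[ids[3]], "<unk>")
})

test_that("vocabulary, merge-table and corpus files round-trip", {
  mols <- fixture_generated_molecules(100)
  tok <- fit_tokenizer(tokenizer_spec("bpe", "smiles", min_substring_freq = 15), mols)
  vp <- withr::local_tempfile(); mp <- withr::local_tempfile()
  cp <- withr::local_tempfile()
  write_vocabulary(tok$vocab, vp)
  v2 <- read_vocabulary(vp)
  expect_identical(v2$tokens, tok$vocab$tokens)
  expect_identical(v2$counts, tok$vocab$counts)
  expect_identical(v2$tokens[1:6], c("<pad>", "<unk>", "<bos>", "<eos>", "?", "."))
  write_merge_table(tok$merges, mp)
  expect_identical(read_merge_table(mp), tok$merges)
  write_tokenized_corpus(tok, mols[1:5], cp)
  lines <- readLines(cp)
  expect_identical(gsub(" ", "", lines), mols[1:5])
})
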