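# Static token embeddings pre-trained on single-molecule corpora, for the
# frozen-input-embedding condition of the translator.

#' Build a single-molecule training corpus
#'
#' Extracts every individual molecule (reactants, reagents and products
#' each contribute separately) from a reaction dataset, converts it to the
#' tokenizer's dialect, and tokenizes it. Sequences never contain the "."
#' separator, since each covers exactly one molecule.
#'
#' @param records a reaction tibble from [generate_reactions()].
#' @param tok a fitted or unfitted [tokenizer_spec()]; its `dialect` decides
#'   whether molecules are converted to SELFIES first.
#' @return a list of token vectors, one per molecule occurrence.
#' @export
build_molecule_corpus <- function(records, tok) {
  if (nrow(records) == 0L) abort_config("cannot build a corpus from zero records")
  mols <- unlist(lapply(seq_len(nrow(records)), function(i) {
    c(records$reactants[[i]], records$reagents[[i]], records$products[[i]])
  }), use.names = FALSE)
  if (tok$dialect == "selfies") mols <- vapply(mols, to_selfies, character(1))
  if (length(tok$merges) > 0L || !is.null(tok$vocab))
    lapply(mols, function(m) tokenize_string(tok, m))
  else
    lapply(mols, atom_tokenize, dialect = tok$dialect)
}

#' Train skip-gram token embeddings
#'
#' Word2vec-style skip-gram with negative sampling, run single-threaded
#' with a private seeded generator so results are reproducible. Special
#' tokens (which never occur inside single-molecule sequences) are added
#' with zero vectors so the translator's frozen input layer covers its
#' whole vocabulary.
#'
#' @param corpus list of token vectors from [build_molecule_corpus()].
#' @param dim embedding dimension (the full-scale preset is 256; smaller
#'   values are appropriate for desk-scale vocabularies).
#' @param window context window half-width (default 5).
#' @param epochs,negatives,lr skip-gram training settings (recorded in the
#'   returned metadata).
#' @param seed integer seed.
#' @return a list of class `rxn_embedding_table`: `vectors` (matrix with
#'   token rownames), `dim`, and `meta`.
#' @export
train_embeddings <- function(corpus, dim = 256L, window = 5L, epochs = 10L,
                             negatives = 5L, lr = 0.025, seed = 1L) {
  if (length(corpus) == 0L) abort_config("cannot train embeddings on an empty corpus")
  tokens <- sort(unique(unlist(corpus, use.names = FALSE)))
  ids <- lapply(corpus, function(seq) match(seq, tokens))
  W <- sgns_train(ids, length(tokens), as.integer(dim), as.integer(window),
                  as.integer(epochs), as.integer(negatives), lr,
                  as.integer(seed))
  rownames(W) <- tokens
  specials <- setdiff(VOCAB_SPECIALS, tokens)
  Z <- matrix(0, nrow = length(specials), ncol = dim,
              dimnames = list(specials, NULL))
  structure(
    list(vectors = rbind(W, Z), dim = as.integer(dim),
         meta = list(architecture = "skip-gram negative sampling",
                     window = window, epochs = epochs,
                     negatives = negatives, lr = lr, seed = seed)),
    class = "rxn_embedding_table"
  )
}

#' @export
print.rxn_embedding_table <- function(x, ...) {
  cat(sprintf("<rxn_embedding_table: %d tokens x %d dims (%s)>\n",
              nrow(x$vectors), x$dim, x$meta$architecture))
  invisible(x)
}

#' Cosine similarity between two embedded tokens
#' @param table an `rxn_embedding_table`.
#' @param a,b token strings.
#' @return the cosine similarity, or `NA` if a vector has zero norm.
#' @export
embedding_similarity <- function(table, a, b) {
  va <- table$vectors[a, ]; vb <- table$vectors[b, ]
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(va * vb) / (na * nb)
}

#' Write and read embeddings in the standard word-vector text format
#'
#' Header line `n_tokens dim`, then one `token v1 ... vd` line per token.
#'
#' @param table an `rxn_embedding_table`.
#' @param path file path.
#' @export
write_embeddings <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(table$vectors), table$dim), con)
  for (i in seq_len(nrow(table$vectors))) {
    writeLines(paste(rownames(table$vectors)[i],
                     paste(format(table$vectors[i, ], digits = 8, trim = TRUE,
                                  scientific = FALSE), collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  parts <- strsplit(lines[-1], " ", fixed = TRUE)
  W <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(hdr[2])))
  rownames(W) <- vapply(parts, `[`, character(1), 1L)
  structure(list(vectors = W, dim = hdr[2], meta = list(source = path)),
            class = "rxn_embedding_table")
}
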