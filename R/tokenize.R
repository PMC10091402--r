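# Atom-level and pair-encoding tokenizers over SMILES or SELFIES strings,
# with frequency-thresholded vocabulary construction. Token concatenation
# always reconstructs the input exactly, in both schemes and both dialects.

VOCAB_SPECIALS <- c("<pad>", "<unk>", "<bos>", "<eos>", "?", ".")

.smiles_token_regex <- paste0(
  "\\[[^][]*\\]|Br|Cl|%\\d{2}|[BCNOPSFI]|[bcnops]|\\d|",
  "[-=#:()./\\\\+*@]"
)
.selfies_token_regex <- "\\[[^][]*\\]|\\.|\\?"

#' Atom-level tokenization of molecule strings
#'
#' SMILES: bracket expressions, two-letter elements (Cl, Br), ring-closure
#' digits (including `%nn`), bond symbols, and parentheses each form one
#' token. SELFIES: each `[...]` group is one token. The "." separator and
#' the fallback "?" are tokens in both dialects.
#'
#' @param s a molecule or reaction string.
#' @param dialect `"smiles"` or `"selfies"`.
#' @return character vector of tokens whose concatenation equals `s`.
#' @examples
#' atom_tokenize("CC(=O)O")
#' @export
atom_tokenize <- function(s, dialect = c("smiles", "selfies")) {
  dialect <- match.arg(dialect)
  if (!nzchar(s)) return(character(0))
  rx <- if (dialect == "smiles") .smiles_token_regex else .selfies_token_regex
  toks <- regmatches(s, gregexpr(rx, s))[[1]]
  if (paste(toks, collapse = "") != s)
    abort_rxn(sprintf("string cannot be tokenized losslessly: %s", substr(s, 1, 60)),
              class = "rxn_tokenization_error")
  toks
}

# Tokens that pair-encoding merges must never absorb: molecule separators,
# the fallback token, and the special symbols themselves.
.unmergeable <- function() c(VOCAB_SPECIALS)

merge_pair_in_seq <- function(seq, a, b) {
  n <- length(seq)
  if (n < 2L) return(seq)
  out <- character(n)
  j <- 0L; i <- 1L
  while (i <= n) {
    if (i < n && seq[i] == a && seq[i + 1L] == b) {
      j <- j + 1L; out[j] <- paste0(a, b); i <- i + 2L
    } else {
      j <- j + 1L; out[j] <- seq[i]; i <- i + 1L
    }
  }
  out[seq_len(j)]
}

count_adjacent_pairs <- function(corpus, blocked) {
  keys <- unlist(lapply(corpus, function(seq) {
    n <- length(seq)
    if (n < 2L) return(character(0))
    a <- seq[-n]; b <- seq[-1L]
    keep <- !(a %in% blocked) & !(b %in% blocked)
    paste(a[keep], b[keep], sep = "\x1f")
  }), use.names = FALSE)
  if (length(keys) == 0L) return(integer(0))
  table(keys)
}

#' Learn a pair-encoding merge table from a tokenized corpus
#'
#' Iteratively merges the most frequent adjacent token pair occurring within
#' single molecules (merges never cross the "." separator or absorb special
#' tokens). Merging stops when no pair's corpus frequency reaches
#' `min_substring_freq`. Ties between equally frequent pairs break
#' lexicographically, making learning deterministic for a fixed corpus.
#'
#' @param corpus list of token vectors (from [atom_tokenize()]).
#' @param min_substring_freq minimum corpus frequency for a merge (the
#'   vocabulary rule used at full corpus scale is 2000 occurrences; at small
#'   scale it is a free knob).
#' @param max_merges safety cap on the number of merges learned.
#' @return list with `merges` (list of `c(left, right)` in learned order)
#'   and `corpus` (the corpus after all merges).
#' @export
train_bpe <- function(corpus, min_substring_freq = 2000L, max_merges = 10000L) {
  if (length(corpus) == 0L) abort_config("cannot train pair encoding on an empty corpus")
  if (min_substring_freq < 1L) abort_config("min_substring_freq must be >= 1")
  blocked <- .unmergeable()
  merges <- list()
  repeat {
    if (length(merges) >= max_merges) break
    tab <- count_adjacent_pairs(corpus, blocked)
    if (length(tab) == 0L) break
    top <- max(tab)
    if (top < min_substring_freq) break
    best <- sort(names(tab)[tab == top])[1L]
    ab <- strsplit(best, "\x1f", fixed = TRUE)[[1]]
    merges[[length(merges) + 1L]] <- ab
    corpus <- lapply(corpus, merge_pair_in_seq, a = ab[1], b = ab[2])
  }
  list(merges = merges, corpus = corpus)
}

apply_merges <- function(seq, merges) {
  for (ab in merges) seq <- merge_pair_in_seq(seq, ab[1], ab[2])
  seq
}

#' Construct a tokenizer
#'
#' @param scheme `"atom"` or `"bpe"`.
#' @param dialect `"smiles"` or `"selfies"`.
#' @param min_substring_freq merge-frequency threshold for `"bpe"`.
#' @return an object of class `rxn_tokenizer`; for `"bpe"` it must be fitted
#'   with [fit_tokenizer()] before use.
#' @export
tokenizer_spec <- function(scheme = c("atom", "bpe"),
                           dialect = c("smiles", "selfies"),
                           min_substring_freq = 2000L) {
  structure(
    list(scheme = match.arg(scheme), dialect = match.arg(dialect),
         min_substring_freq = as.integer(min_substring_freq),
         merges = list(), vocab = NULL),
    class = "rxn_tokenizer"
  )
}

#' @export
print.rxn_tokenizer <- function(x, ...) {
  cat(sprintf("<rxn_tokenizer: %s / %s, %d merges, %s>\n",
              x$scheme, x$dialect, length(x$merges),
              if (is.null(x$vocab)) "unfitted" else
                sprintf("vocabulary of %d tokens", length(x$vocab$tokens))))
  invisible(x)
}

#' Fit a tokenizer on a training corpus
#'
#' Learns pair-encoding merges (for the `"bpe"` scheme) and builds the
#' vocabulary: special tokens first, then all base atom-level tokens, then
#' merged substrings, each with its corpus frequency after merging.
#'
#' @param tok an [tokenizer_spec()] object.
#' @param strings character vector of training strings (sources and targets).
#' @return the fitted tokenizer, with `$vocab` populated.
#' @export
fit_tokenizer <- function(tok, strings) {
  stopifnot(inherits(tok, "rxn_tokenizer"))
  if (length(strings) == 0L) abort_config("cannot fit a tokenizer on an empty corpus")
  corpus <- lapply(strings, atom_tokenize, dialect = tok$dialect)
  base_tokens <- sort(unique(unlist(corpus, use.names = FALSE)))
  merged_corpus <- corpus
  if (tok$scheme == "bpe") {
    fit <- train_bpe(corpus, min_substring_freq = tok$min_substring_freq)
    tok$merges <- fit$merges
    merged_corpus <- fit$corpus
  }
  counts_tab <- table(unlist(merged_corpus, use.names = FALSE))
  merged_tokens <- vapply(tok$merges, function(ab) paste0(ab[1], ab[2]), character(1))
  tokens <- c(VOCAB_SPECIALS,
              setdiff(base_tokens, VOCAB_SPECIALS),
              setdiff(merged_tokens, base_tokens))
  tokens <- tokens[!duplicated(tokens)]
  counts <- as.integer(counts_tab[tokens])
  counts[is.na(counts)] <- 0L
  tok$vocab <- list(tokens = tokens, counts = counts, specials = VOCAB_SPECIALS)
  tok
}

#' Tokenize, encode and decode with a fitted tokenizer
#'
#' `tokenize_string()` returns tokens (merges applied greedily in learned
#' order); `encode_string()` returns 1-based vocabulary ids with the number
#' of out-of-vocabulary tokens in attribute `"n_unk"`; `decode_ids()`
#' inverts encoding by concatenation, so `decode_ids(encode_string(s))`
#' is byte-identical to `s` whenever no token maps to `<unk>`.
#'
#' @param tok a fitted tokenizer.
#' @param s a string.
#' @return see details above.
#' @export
tokenize_string <- function(tok, s) {
  seq <- atom_tokenize(s, dialect = tok$dialect)
  if (length(tok$merges) > 0L) seq <- apply_merges(seq, tok$merges)
  seq
}

#' @rdname tokenize_string
#' @export
encode_string <- function(tok, s) {
  if (is.null(tok$vocab)) abort_config("tokenizer has no vocabulary; call fit_tokenizer() first")
  seq <- tokenize_string(tok, s)
  ids <- match(seq, tok$vocab$tokens)
  n_unk <- sum(is.na(ids))
  ids[is.na(ids)] <- match("<unk>", tok$vocab$tokens)
  structure(as.integer(ids), n_unk = n_unk)
}

#' @rdname tokenize_string
#' @param ids integer vector of vocabulary ids.
#' @export
decode_ids <- function(tok, ids) {
  paste(tok$vocab$tokens[ids], collapse = "")
}

# --- vocabulary / merge-table / corpus files (plain-text conventions) -------

#' Read and write vocabulary, merge-table and tokenized-corpus files
#'
#' Vocabulary files hold one `token<TAB>count` line per token, specials
#' first. Merge tables hold one `left<TAB>right` merge per line in learned
#' order. Tokenized corpora are space-separated tokens, one sample per line
#' (the parallel-text convention of NMT toolkits).
#'
#' @param vocab,path,merges,strings,tok see individual functions.
#' @name token_files
NULL

#' @rdname token_files
#' @export
write_vocabulary <- function(vocab, path) {
  writeLines(paste(vocab$tokens, vocab$counts, sep = "\t"), path)
  invisible(path)
}

#' @rdname token_files
#' @export
read_vocabulary <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  list(tokens = vapply(parts, `[`, character(1), 1L),
       counts = as.integer(vapply(parts, `[`, character(1), 2L)),
       specials = VOCAB_SPECIALS)
}

#' @rdname token_files
#' @export
write_merge_table <- function(merges, path) {
  writeLines(vapply(merges, paste, character(1), collapse = "\t"), path)
  invisible(path)
}

#' @rdname token_files
#' @export
read_merge_table <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
}

#' @rdname token_files
#' @export
write_tokenized_corpus <- function(tok, strings, path) {
  writeLines(vapply(strings, function(s) paste(tokenize_string(tok, s), collapse = " "),
                    character(1)), path)
  invisible(path)
}
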