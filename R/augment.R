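# Source-only data augmentation: k-fold training sets built from random
# non-canonical SMILES re-serializations and random permutations of the
# source molecules. Targets are never modified.

#' Augmentation specification
#'
#' @param factor dataset-size multiplier (1 reproduces the input exactly;
#'   the standard grid is 1, 2, 5, 10, 20 but any integer >= 1 is allowed).
#' @param permute_molecules randomly permute the order of source molecules
#'   in each variant.
#' @param randomize_strings re-serialize each source molecule as a random
#'   non-canonical string in each variant.
#' @param preserve_order keep source molecules in their original order even
#'   when variants are drawn (an alternative scheme for tasks where molecule
#'   order is informative); overrides `permute_molecules`.
#' @param seed integer seed; augmentation is deterministic per seed.
#' @return a list of class `rxn_augmentation_spec`.
#' @export
augmentation_spec <- function(factor = 1L, permute_molecules = TRUE,
                              randomize_strings = TRUE, preserve_order = FALSE,
                              seed = 1L) {
  if (factor < 1L) abort_config("augmentation factor must be >= 1")
  structure(
    list(factor = as.integer(factor), permute_molecules = permute_molecules,
         randomize_strings = randomize_strings, preserve_order = preserve_order,
         seed = as.integer(seed)),
    class = "rxn_augmentation_spec"
  )
}

#' Augment task samples on the source side only
#'
#' The output contains, for each input sample, the original (canonical,
#' unpermuted) sample followed by `factor - 1` variants whose source
#' molecules are independently string-randomized and whose order is
#' randomly permuted. Variants are drawn with replacement from the
#' randomized-string space (small molecules have few enumerations, so
#' duplicates can occur). Targets are byte-identical to the originals, and
#' every variant's source encodes the same canonical molecule multiset as
#' its original.
#'
#' @param samples a task-sample tibble (from [build_task_samples()]).
#' @param spec an [augmentation_spec()].
#' @return a tibble of `factor * nrow(samples)` samples; column
#'   `origin` holds the input row each sample derives from.
#' @export
augment_dataset <- function(samples, spec) {
  stopifnot(inherits(spec, "rxn_augmentation_spec"))
  n <- nrow(samples)
  if (spec$factor == 1L) {
    out <- samples
    out$origin <- seq_len(n)
    return(out)
  }
  with_seed(spec$seed, {
    src_mols <- lapply(samples$source, split_molecules)
    copies <- vector("list", spec$factor)
    copies[[1]] <- cbind_origin(samples, seq_len(n))
    for (cp in seq.int(2L, spec$factor)) {
      new_src <- vapply(seq_len(n), function(i) {
        mols <- src_mols[[i]]
        if (spec$randomize_strings) {
          mols <- vapply(seq_along(mols), function(j) {
            tryCatch(randomize_smiles(mols[j]),
                     rxn_invalid_molecule = function(e) abort_rxn(
                       sprintf("sample %d: source molecule '%s' cannot be parsed",
                               i, mols[j]),
                       class = "rxn_invalid_molecule"))
          }, character(1))
        }
        if (spec$permute_molecules && !spec$preserve_order && length(mols) > 1L)
          mols <- mols[sample.int(length(mols))]
        join_molecules(mols)
      }, character(1))
      variant <- samples
      variant$source <- new_src
      copies[[cp]] <- cbind_origin(variant, seq_len(n))
    }
    do.call(rbind, copies)
  })
}

cbind_origin <- function(samples, origin) {
  samples$origin <- origin
  samples
}

#' Write and read parallel source/target text files
#'
#' The NMT convention: two order-aligned files, one sample per line.
#'
#' @param samples a task-sample tibble.
#' @param src_path,tgt_path file paths.
#' @return `write_parallel_text()`: invisibly, the two paths;
#'   `read_parallel_text()`: a tibble with `source` and `target`.
#' @export
write_parallel_text <- function(samples, src_path, tgt_path) {
  writeLines(samples$source, src_path)
  writeLines(samples$target, tgt_path)
  invisible(c(src_path, tgt_path))
}

#' @rdname write_parallel_text
#' @export
read_parallel_text <- function(src_path, tgt_path) {
  src <- readLines(src_path); tgt <- readLines(tgt_path)
  if (length(src) != length(tgt))
    abort_rxn("source and target files have different lengths",
              class = "rxn_parse_error")
  tibble::tibble(source = src, target = tgt)
}
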