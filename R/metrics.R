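# Evaluation suite: strict/lenient top-k accuracy over canonical molecule
# sets, round-trip accuracy against a matched forward model, molecule-level
# precision/recall/F1 at rank k, and reagent-count binned analysis with
# weighted pooling.

#' Construct a prediction record
#'
#' One evaluated test sample: its source, its target, and the ranked
#' n-best candidate list produced by a model, with optional task metadata
#' used by round-trip and binned evaluation.
#'
#' @param source,target the sample's source and target strings.
#' @param candidates character vector of candidate strings, best first.
#' @param scores numeric scores, non-increasing with rank.
#' @param task,include_reagents task metadata.
#' @param true_reagents character vector of the sample's true reagent
#'   molecules (needed for round-trip under the with-reagents setting and
#'   for binning).
#' @param products character vector of the sample's true product molecules
#'   (needed for round-trip).
#' @return a list of class `rxn_prediction_record`.
#' @export
prediction_record <- function(source, target, candidates, scores = NULL,
                              task = NA_character_, include_reagents = NA,
                              true_reagents = NULL, products = NULL) {
  if (!nzchar(target)) abort_config("prediction record requires a non-empty target")
  if (is.null(scores)) scores <- rev(seq_along(candidates))
  if (is.unsorted(rev(scores))) abort_config("candidate scores must be non-increasing")
  structure(
    list(source = source, target = target, candidates = as.character(candidates),
         scores = as.numeric(scores), task = task,
         include_reagents = include_reagents,
         true_reagents = true_reagents, products = products),
    class = "rxn_prediction_record"
  )
}

# Canonical molecule set of a "."-joined string; unparseable molecules are
# returned separately so callers can choose strict or lenient handling.
canonical_molecule_set <- function(s) {
  mols <- split_molecules(s)
  out <- character(0); n_invalid <- 0L
  for (m in mols) {
    c <- tryCatch(canonicalize_smiles(m), rxn_invalid_molecule = function(e) NULL)
    if (is.null(c)) n_invalid <- n_invalid + 1L else out <- c(out, c)
  }
  list(set = unique(out), n_invalid = n_invalid, n_molecules = length(mols))
}

#' Strict and lenient candidate matching
#'
#' `strict_hit()`: the set of canonical molecules in the candidate equals
#' the set in the target — every target molecule is predicted and nothing
#' extra is; a candidate containing any unparseable molecule is a miss.
#' `lenient_hit()`: at least one predicted molecule matches a target
#' molecule; unparseable candidate molecules are ignored individually.
#'
#' @param candidate,target "."-joined molecule strings.
#' @return `TRUE` or `FALSE`.
#' @examples
#' strict_hit("CCO.CC", "CC.CCO")   # order-invariant: TRUE
#' lenient_hit("CCO.CCC", "CCO.N")  # shared molecule: TRUE
#' @export
strict_hit <- function(candidate, target) {
  cand <- canonical_molecule_set(candidate)
  if (cand$n_invalid > 0L || length(cand$set) == 0L) return(FALSE)
  tgt <- canonical_molecule_set(target)
  setequal(cand$set, tgt$set)
}

#' @rdname strict_hit
#' @export
lenient_hit <- function(candidate, target) {
  cand <- canonical_molecule_set(candidate)
  tgt <- canonical_molecule_set(target)
  length(intersect(cand$set, tgt$set)) > 0L
}

#' Top-k accuracy over prediction records
#'
#' The proportion of records with at least one hit among the first `k`
#' candidates (records with fewer than `k` candidates use all available).
#'
#' @param records list of [prediction_record()] objects.
#' @param k rank cutoff.
#' @param mode `"strict"` or `"lenient"`.
#' @return a fraction in \[0, 1\].
#' @export
topk_accuracy <- function(records, k, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  if (length(records) == 0L) abort_undefined_metric("top-k accuracy of an empty record list")
  if (k < 1L) abort_config("k must be >= 1")
  hit_fn <- if (mode == "strict") strict_hit else lenient_hit
  hits <- vapply(records, function(r) {
    top <- utils::head(r$candidates, k)
    any(vapply(top, hit_fn, logical(1), target = r$target))
  }, logical(1))
  mean(hits)
}

#' Round-trip accuracy against a matched forward model
#'
#' For each reactant-prediction record, the rank-1 predicted reactants —
#' concatenated with the true reagents when the record's reagent setting is
#' on — are fed to the forward (product-prediction) model; the record
#' counts as a success iff the forward model's rank-1 product strictly
#' matches the record's true product. Because a forward model accepts any
#' precursor set it can map to the product, this credits alternative
#' synthesis routes that strict top-1 matching rejects.
#'
#' @param records list of [prediction_record()] objects carrying `products`
#'   (and `true_reagents` when `include_reagents` is `TRUE`).
#' @param forward_model `function(source_string) -> product string`, e.g.
#'   [template_forward_oracle()] or [translator_as_forward_model()]. Must
#'   be the matched model: same augmentation factor and reagent setting as
#'   the reactant model under evaluation.
#' @return the success fraction.
#' @export
roundtrip_accuracy <- function(records, forward_model) {
  if (length(records) == 0L) abort_undefined_metric("round-trip accuracy of an empty record list")
  succ <- vapply(records, function(r) {
    if (is.null(r$products)) abort_config("round-trip requires records with true products")
    mols <- split_molecules(r$candidates[1])
    if (isTRUE(r$include_reagents)) {
      if (is.null(r$true_reagents))
        abort_config("reagent setting is on but record carries no true_reagents")
      mols <- c(mols, r$true_reagents)
    }
    pred_product <- forward_model(join_molecules(mols))
    nzchar(pred_product) && strict_hit(pred_product, join_molecules(r$products))
  }, logical(1))
  mean(succ)
}

#' Molecule-level precision, recall and F1 at rank k
#'
#' Pools the `N` unique canonical molecules across a record's top-k
#' candidates (unparseable molecules are dropped from the pool and counted
#' as invalid); with `T` of them matching any of the `M` unique target
#' molecules, returns `P = T/N`, `R = T/M`, `F = 2PR/(P+R)` (with `P = 0`
#' when `N = 0` and `F = 0` when `P + R = 0`).
#'
#' @param record a [prediction_record()].
#' @param k rank cutoff.
#' @return named numeric: `P`, `R`, `F1`, plus counts `T`, `N`, `M` and
#'   `n_invalid`.
#' @export
prf_at_k <- function(record, k) {
  if (k < 1L) abort_config("k must be >= 1")
  tgt <- canonical_molecule_set(record$target)
  M <- length(tgt$set)
  if (M == 0L) abort_undefined_metric("record has no valid target molecules")
  top <- utils::head(record$candidates, k)
  pred <- character(0); n_invalid <- 0L
  for (cand in top) {
    cs <- canonical_molecule_set(cand)
    pred <- c(pred, cs$set)
    n_invalid <- n_invalid + cs$n_invalid
  }
  pred <- unique(pred)
  N <- length(pred)
  T_ <- length(intersect(pred, tgt$set))
  P <- if (N == 0L) 0 else T_ / N
  R <- T_ / M
  F1 <- if (P + R == 0) 0 else 2 * P * R / (P + R)
  c(P = P, R = R, F1 = F1, T = T_, N = N, M = M, n_invalid = n_invalid)
}

#' Binned precision/recall/F1 with weighted pooling
#'
#' Bins records by their number of target reagent molecules, averages
#' per-record P/R/F within each bin, discards bins with more than
#' `max_bin` reagents or fewer than `min_bin_n` records, and pools the
#' retained bins weighting each bin mean by its record count.
#'
#' @param records list of [prediction_record()] objects (reagent task: the
#'   target molecules are the reagents).
#' @param k rank cutoff.
#' @param max_bin largest reagent count retained (default 12).
#' @param min_bin_n smallest bin size retained (default 20).
#' @return a list with `bins` (tibble: `n_reagents`, `n`, `P`, `R`, `F1`)
#'   and `pooled` (named numeric `P`, `R`, `F1`).
#' @export
bin_and_pool <- function(records, k = 1L, max_bin = 12L, min_bin_n = 20L) {
  if (length(records) == 0L) abort_undefined_metric("binned metrics of an empty record list")
  key <- vapply(records, function(r) length(split_molecules(r$target)), integer(1))
  prf <- t(vapply(records, prf_at_k, numeric(7), k = k))
  bins <- sort(unique(key))
  rows <- lapply(bins, function(b) {
    i <- key == b
    tibble::tibble(n_reagents = b, n = sum(i),
                   P = mean(prf[i, "P"]), R = mean(prf[i, "R"]),
                   F1 = mean(prf[i, "F1"]))
  })
  bins_tbl <- do.call(rbind, rows)
  retained <- bins_tbl[bins_tbl$n_reagents <= max_bin & bins_tbl$n >= min_bin_n, ,
                       drop = FALSE]
  if (nrow(retained) == 0L) abort_undefined_metric("no bins retained after filtering")
  w <- retained$n
  pooled <- c(P = sum(retained$P * w) / sum(w),
              R = sum(retained$R * w) / sum(w),
              F1 = sum(retained$F1 * w) / sum(w))
  list(bins = bins_tbl, retained = retained, pooled = pooled)
}

#' Full evaluation report
#'
#' Strict and lenient top-k accuracy for `k` in `ks`, the
#' invalid-candidate-molecule rate over the ranks examined, and the sample
#' count.
#'
#' @param records list of [prediction_record()] objects.
#' @param ks rank cutoffs (default 1..10).
#' @return a list with `topk` (tibble: `k`, `strict`, `lenient`),
#'   `invalid_candidate_rate`, and `n`.
#' @export
evaluation_report <- function(records, ks = 1:10) {
  if (length(records) == 0L) abort_undefined_metric("report over an empty record list")
  topk <- tibble::tibble(
    k = as.integer(ks),
    strict = vapply(ks, function(k) topk_accuracy(records, k, "strict"), numeric(1)),
    lenient = vapply(ks, function(k) topk_accuracy(records, k, "lenient"), numeric(1))
  )
  kmax <- max(ks)
  counts <- vapply(records, function(r) {
    tot <- 0L; bad <- 0L
    for (cand in utils::head(r$candidates, kmax)) {
      cs <- canonical_molecule_set(cand)
      tot <- tot + cs$n_molecules; bad <- bad + cs$n_invalid
    }
    c(tot, bad)
  }, numeric(2))
  list(topk = topk,
       invalid_candidate_rate = if (sum(counts[1, ]) == 0) 0 else
         sum(counts[2, ]) / sum(counts[1, ]),
       n = length(records))
}

#' Write an evaluation report to JSON and a per-bin CSV
#'
#' @param report a list from [evaluation_report()].
#' @param json_path output JSON path.
#' @param bins optional result of [bin_and_pool()]; when given, its bin
#'   table is written next to the JSON as `<json_path stem>_bins.csv`.
#' @return the JSON path, invisibly.
#' @export
write_evaluation_report <- function(report, json_path, bins = NULL) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    abort_config("writing JSON reports requires the jsonlite package")
  out <- list(
    n = report$n,
    invalid_candidate_rate = report$invalid_candidate_rate,
    topk = as.data.frame(report$topk)
  )
  if (!is.null(bins)) out$pooled <- as.list(bins$pooled)
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(bins)) {
    csv <- sub("\\.json$", "", json_path)
    utils::write.csv(as.data.frame(bins$bins), paste0(csv, "_bins.csv"),
                     row.names = FALSE)
  }
  invisible(json_path)
}

#' Write and read n-best prediction files
#'
#' For each source, `k` consecutive lines `rank<TAB>score<TAB>candidate`.
#'
#' @param records list of [prediction_record()] objects.
#' @param path file path.
#' @return `write_predictions()`: the path invisibly; `read_predictions()`:
#'   a list of `(rank, score, candidate)` tibbles, one per source.
#' @export
write_predictions <- function(records, path) {
  lines <- unlist(lapply(records, function(r) {
    sprintf("%d\t%.6f\t%s", seq_along(r$candidates), r$scores, r$candidates)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rank <- as.integer(vapply(parts, `[`, character(1), 1L))
  groups <- cumsum(rank == 1L)
  lapply(split(seq_along(lines), groups), function(i) {
    tibble::tibble(rank = rank[i],
                   score = as.numeric(vapply(parts[i], `[`, character(1), 2L)),
                   candidate = vapply(parts[i], `[`, character(1), 3L))
  })
}
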