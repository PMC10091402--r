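# Two-group expert label tabulation over round-trip-positive, strict-miss
# predictions. Each selected reaction is judged once by each of two expert
# groups with one of three labels: wrong, semi-correct, or correct;
# "not wrong" means semi-correct or correct.

.agreement_labels <- c("wrong", "semi", "correct")

#' Select reactions for expert review
#'
#' The interesting disagreement set: reactions whose rank-1 predicted
#' reactants do not strictly match the recorded target but succeed in the
#' round-trip experiment — candidate alternative synthesis routes.
#'
#' @param records list of [prediction_record()] objects.
#' @param forward_model matched forward model (see [roundtrip_accuracy()]).
#' @return integer indices into `records`.
#' @export
select_agreement_candidates <- function(records, forward_model) {
  idx <- integer(0)
  for (i in seq_along(records)) {
    r <- records[[i]]
    strict <- strict_hit(r$candidates[1], r$target)
    if (strict) next
    rt <- roundtrip_accuracy(records[i], forward_model) == 1
    if (rt) idx <- c(idx, i)
  }
  idx
}

#' Tabulate two-group expert labels
#'
#' Counts how often both groups judged a prediction "not wrong"
#' (semi-correct or correct), both judged it wrong, or the groups
#' contradicted each other; the three categories partition the label set.
#' Percentages are reported both as exact fractions and rounded to integer
#' percent.
#'
#' @param labels a data frame with columns `reaction_id`, `group_a`,
#'   `group_b`; labels must be `"wrong"`, `"semi"` or `"correct"`.
#' @return a list with `n`, `counts` (named: `both_not_wrong`,
#'   `both_wrong`, `contradictory`), `fractions`, `percent` (integer
#'   rounded), and per-group not-wrong rates.
#' @export
tabulate_agreement <- function(labels) {
  if (nrow(labels) == 0L) abort_undefined_metric("cannot tabulate an empty label set")
  bad <- !(labels$group_a %in% .agreement_labels) | !(labels$group_b %in% .agreement_labels)
  if (any(bad))
    abort_config(sprintf("unknown label in row %d (expected wrong/semi/correct)",
                         which(bad)[1]))
  a_ok <- labels$group_a != "wrong"
  b_ok <- labels$group_b != "wrong"
  counts <- c(both_not_wrong = sum(a_ok & b_ok),
              both_wrong = sum(!a_ok & !b_ok),
              contradictory = sum(xor(a_ok, b_ok)))
  n <- nrow(labels)
  fractions <- counts / n
  list(n = n, counts = counts, fractions = fractions,
       percent = round(100 * fractions),
       group_not_wrong = c(group_a = mean(a_ok), group_b = mean(b_ok)))
}

#' Read and write expert label files
#'
#' CSV with columns `reaction_id,group_a,group_b`.
#'
#' @param labels a label data frame.
#' @param path file path.
#' @export
write_agreement_labels <- function(labels, path) {
  utils::write.csv(labels[, c("reaction_id", "group_a", "group_b")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_agreement_labels
#' @export
read_agreement_labels <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    colClasses = "character"))
}
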