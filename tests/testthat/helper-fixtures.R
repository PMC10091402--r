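# Shared fixtures: everything is generated in code at test time.

# A small, diverse set of valid molecules drawn from the synthetic library
# plus hand-picked structures covering brackets, charges, rings and
# branches.
fixture_molecules <- function() {
  c("C", "CC", "CCO", "CCN", "CC(C)C", "CC(C)(C)C", "C#N", "C=CC",
    "CC(=O)O", "CC(=O)OCC", "CC(=O)NC", "OS(=O)(=O)O", "CN(C)C=O",
    "C1CCCCC1", "C1CCOC1", "C1COCCO1", "CC1=CC=CC=C1", "C1=CC=CC=C1CO",
    "BrCC(Br)C1CCC(CC1)C(=O)O", "CC(F)C", "ClCCl", "[O-]C(=O)C",
    "CC(C)(C)OC(=O)NCC", "C1CCC2(CC1)CC(=O)O2")
}

# Molecules from the generator itself (as-constructed forms).
fixture_generated_molecules <- function(n, seed = 11) {
  rec <- generate_reactions(synthetic_config(max(200L, n * 3L), seed = seed))
  mols <- unique(unlist(c(rec$reactants, rec$products, rec$reagents)))
  mols[seq_len(min(n, length(mols)))]
}

# Independent canonical-equality oracle through Open Babel: two strings
# denote the same molecule iff their Open Babel canonical SMILES agree.
ob_canonical <- function(s) {
  out <- ChemmineOB::convertFormat("SMI", "CAN", s)
  sub("\t.*$", "", sub("\n$", "", out))
}

# A tiny deterministic prediction-record fixture generator used by metric
# property tests: targets and candidates are "."-joined subsets of a
# molecule pool, so hits at controlled ranks arise naturally.
random_prediction_records <- function(n_records, pool = fixture_molecules(),
                                      max_rank = 5) {
  lapply(seq_len(n_records), function(i) {
    tgt <- sample(pool, sample(1:3, 1))
    cands <- vapply(seq_len(max_rank), function(r) {
      if (stats::runif(1) < 0.4) {
        join_molecules(sample(tgt))               # exact hit, permuted
      } else if (stats::runif(1) < 0.5) {
        join_molecules(c(sample(tgt, 1), sample(pool, 1)))  # partial overlap
      } else {
        join_molecules(sample(setdiff(pool, tgt), sample(1:2, 1)))
      }
    }, character(1))
    prediction_record(source = "C", target = join_molecules(tgt),
                      candidates = cands)
  })
}
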