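# rxnpredict

Predictive-scenario analysis for chemical reaction sequence models, in R.

Sequence-to-sequence models treat reaction prediction as translation over
molecule strings: product prediction (reactants → product), single-step
retrosynthesis (product → reactants), and reagent prediction
(reactants + product → reagents). Evaluating such models is subtle —
strict comparison against a reference answer penalizes chemically valid
alternative routes, which round-trip scoring (feed the predicted
precursors to a matched forward model and ask for the original product
back) credits. `rxnpredict` implements the whole scenario grid as tested,
reusable components:

* **Synthetic reactions** — a template-grafting generator whose datasets
  have the statistical shape of large curated reaction corpora
  (1–5 reactants, mean 1.78; 0–21 reagents, mean 3.03, median 3), with a
  deterministic forward transform so an exact oracle forward model exists.
* **Molecule strings** — SMILES parsing, canonicalization, and randomized
  (non-canonical) enumeration over a molecular-graph representation, plus
  a robust SELFIES-style codec with the `"?"` fallback for unencodable
  molecules.
* **Augmentation** — source-only k-fold augmentation by string
  randomization and molecule permutation; targets are never modified.
* **Tokenization** — atom-level and pair-encoding (BPE) tokenizers for
  both dialects, with frequency-thresholded vocabulary construction.
* **Embeddings** — seeded skip-gram token embeddings trained on
  single-molecule corpora, for the frozen-input-embedding condition.
* **Translator** — a compact encoder–decoder transformer (RcppArmadillo,
  gradient-checked) with token-budgeted batching, early stopping on
  validation token accuracy and perplexity, and beam-search n-best
  decoding (beam size 10).
* **Evaluation** — strict/lenient top-k accuracy over canonical molecule
  sets, round-trip accuracy against a matched forward model,
  molecule-level precision/recall/F1 at rank k, reagent-count binning
  with weighted pooling, and two-group expert-label agreement
  tabulation.

The core metric definitions, for a candidate string and target string
split on the `.` separator and canonicalized: a **strict** hit requires
set equality of canonical molecules; a **lenient** hit requires a
non-empty intersection; **top-k accuracy** is the fraction of test
records with a hit among the k best beam candidates; **round-trip
accuracy** is the fraction whose rank-1 predicted reactants (plus true
reagents, when in scope) regenerate the true product at rank 1 of the
matched forward model; and at rank k, over the N unique predicted
molecules and M unique target molecules with T in common,
P = T/N, R = T/M, F = 2PR/(P+R).

## A worked example

```r
library(rxnpredict)

rec <- generate_reactions(synthetic_config(5000, seed = 1))
sp  <- split_dataset(rec, c(0.85, 0.0625, 0.0875), seed = 1)
fwd <- lapply(sp, build_task_samples, task = "product")
ret <- lapply(sp, build_task_samples, task = "reactant")

mf <- translator_train(fwd$train, fwd$valid, model_config("desk", seed = 0, max_steps = 2200))
mr <- translator_train(ret$train, ret$valid, model_config("desk", seed = 0, max_steps = 2200))

rf <- predictions_to_records(fwd$test, predict(mf, fwd$test$source, k = 10), task = "product")
rr <- predictions_to_records(ret$test, predict(mr, ret$test$source, k = 10), task = "reactant")

evaluation_report(rf, ks = 1:2)$topk
#> # A tibble: 2 × 3
#>       k strict lenient
#>   <int>  <dbl>   <dbl>
#> 1     1  0.931   0.931
#> 2     2  0.977   0.977

rep_r <- evaluation_report(rr, ks = 1:10)
rep_r$topk$strict[1]                              # retro strict top-1
#> [1] 0.9107551
roundtrip_accuracy(rr, template_forward_oracle()) # round-trip, oracle forward model
#> [1] 0.9427918
majority_baseline(fwd$test$target)                # the floor to beat
#> [1] 0.01830664
```

On this synthetic test set the desk-preset forward model reaches 93%
strict top-1 against a 1.8% majority baseline, and retrosynthesis
round-trip accuracy (94.3%) exceeds strict top-1 (91.1%): round-trip
scoring credits predicted precursor sets that are valid under the
template library but differ from the recorded reactants — the behaviour
that motivates using it alongside database-matching metrics.

Expert-label agreement works from a CSV of two labels per reaction:

```r
tab <- tabulate_agreement(labels)   # labels: reaction_id, group_a, group_b
tab$percent
#> both_not_wrong     both_wrong  contradictory
#>             81              4             15
```

## Scope

The package is a desk-scale laboratory for the *pipeline*: task
construction, augmentation, format/tokenization/embedding variants, and
evaluation methodology. GPU-scale training on the full patent-reaction
corpora, and the accuracy tables that come with it, are out of scope; the
methods vignette (`vignettes/reaction-prediction-scenarios.Rmd`) states
the models, the design decisions, and what synthetic-data results do and
do not show.
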