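---
title: "Predictive scenarios for reaction sequence models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive scenarios for reaction sequence models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rxnpredict)
```

# The problem

Sequence-to-sequence ("molecular transformer") models translate reaction
strings: given the reactants of a reaction (optionally with its reagents),
predict the product; given the product, predict the reactants
(single-step retrosynthesis); or given reactants and product, predict the
reagents. How such models should be *evaluated* is as consequential as how
they are trained: a strict string-level comparison against a reference
database penalizes chemically valid alternative routes, while round-trip
scoring — does a matched forward model regenerate the product from the
predicted precursors? — credits them. This package implements the full
scenario grid around that question as reusable, tested components: task
construction, source-side data augmentation, molecule-format and
tokenization variants, static pre-trained embeddings, a compact
encoder–decoder transformer, and the evaluation suite (strict/lenient
top-k, round-trip, molecule-level P/R/F at rank k, reagent-count binning,
expert-label agreement).

Everything runs at desk scale on synthetic reactions, so every stage of
the pipeline is exercised end-to-end by the test suite on one CPU.

# The synthetic reaction generator

Real curated reaction corpora are hundreds of thousands of reactions and
are not shipped here. What the downstream components need from data is its
*shape*, not its chemistry, so `generate_reactions()` draws reactions from
a library of string-grafting templates:

* A curated alphabet of 22 graftable SMILES fragments (alkyl chains,
  branched chains, alicyclic and aromatic rings, ether/amine/thioether
  cores), each starting and ending on an atom with a free valence, so that
  concatenating fragments and linker strings always yields a parseable
  molecule — validity by construction, without a reaction-rule engine.
* Ten templates (esterification, amide coupling, Williamson ether
  synthesis, N-alkylation, a Suzuki-style coupling, ketone reduction,
  alkene hydrogenation, and three multi-component assemblies). A template
  has one functional-group suffix per reactant slot (`C(=O)O`, `O`, `N`,
  `Br`, `B(O)O`, ...) and linker strings; a reactant is
  `fragment + group`, the product is the fragments interleaved with the
  linkers. Reagent pools carry characteristic solvents, bases and
  catalysts (including bracket-atom species such as `[Pd]` and `[Na+]`).
* Template weights realize the reactant-count distribution over 1–5 with
  mean 1.78, sd 0.47 and median 2; reagent counts are drawn from a
  negative binomial with mean 3.03 and sd 2.22 (size
  $\mu^2/(\sigma^2-\mu) \approx 4.84$), truncated at 21 — the tail
  probability beyond 21 is $\approx 1.5\times10^{-6}$, so truncation does
  not disturb the moments. These targets are the printed statistics of the
  curated patent-reaction corpus the generator emulates, chosen once and
  not tuned afterwards.

Because the product is a pure function of the reactant set (the
`template_forward_oracle()` looks each canonical reactant form up, matches
the group multiset to a template signature, and reassembles the product),
a perfect forward predictor exists by construction, and round-trip scoring
has an exact reference model. Canonical-form collisions between
`(fragment, group)` pairs are resolved at library-build time by excluding
the colliding pair, so the lookup is well-defined; reagent pools are
verified disjoint from all reactant forms so appended reagents can never
masquerade as precursors.

What the generator does *not* emulate: reaction mechanisms, selectivity,
atom mapping, the long-tailed molecule-size distribution of patent data,
or multi-product reactions (a `multi_product` switch emits water as a
second product for condensation templates, off by default since curated
corpora are predominantly single-product). Passing tests therefore
demonstrate that the pipeline's machinery is correct, not that any model
quality result transfers to real reaction data.

# Molecule strings

No installed R toolkit provides canonical SMILES together with randomized
SMILES enumeration and SELFIES, so the package implements a molecular
graph toolkit over a documented SMILES subset: the organic subset plus
aromatic lowercase atoms, bracket atoms with isotope/charge/explicit H,
bond orders 1–3 and aromatic, branches, and ring closures. Stereochemistry
is not modelled, and no aromaticity perception is attempted: Kekulé and
aromatic forms are treated as distinct molecules. Within the pipeline this
is sound because all molecules are produced in one consistent convention;
the test suite cross-checks canonical *equality* claims against Open
Babel, an independent toolkit.

* `canonicalize_smiles()` ranks atoms by iterated neighbourhood refinement
  (element, aromaticity, charge, isotope, explicit H, degree, bond-order
  sum, then iterated neighbour ranks), breaks remaining ties by trying
  each member of the first tied class and keeping the lexicographically
  smallest result, and writes the string from the top-ranked root. The
  output is a pure function of the molecular graph, hence idempotent.
* `randomize_smiles()` re-serializes from a uniformly random root atom
  with a random neighbour visit order — the augmentation primitive.
* `to_selfies()`/`from_selfies()` implement a robust bracket-token
  notation with a 16-symbol index alphabet for branch lengths and ring
  distances. The decoder is total on well-formed strings: bond orders are
  truncated to remaining valence, and branch/ring symbols lacking context
  are skipped, so every derivation yields a valid molecule. Molecules
  outside the encodable dialect (aromatic-form rings, elements such as Na
  or Pd) are replaced by the single fallback token `"?"` — the same
  convention used for rare unencodable molecules in real corpora. The
  fragment library deliberately contains two aromatic-form fragments and
  several inorganic reagents so this path is exercised end-to-end.

# Augmentation

`augment_dataset()` performs source-only augmentation: each sample
contributes the original plus `factor − 1` variants whose source molecules
are independently re-rooted and randomly permuted; targets are never
modified (asserted byte-for-byte in tests). Variants are drawn with
replacement — small molecules have very few surface forms, so requiring
distinctness would bias the sampling. Copy #1 is always the untouched
sample, so factor 1 reproduces the input exactly. A `preserve_order`
switch keeps molecule order for tasks where it is informative. Molecule
order and serialization are the only degrees of freedom: every variant's
canonical molecule multiset equals its original's, which is the
chemistry-preservation property the acceptance suite checks on thousands
of variants.

# Tokenization and vocabularies

`atom_tokenize()` applies the standard reaction-transformer rules
(bracket expressions, two-letter elements, `%nn` ring closures, bonds,
parentheses as single tokens; each SELFIES `[...]` group is one token);
concatenating tokens always reconstructs the input, otherwise a
tokenization error is raised. `train_bpe()` implements pair encoding:
iteratively merge the most frequent adjacent pair, stopping when no pair
reaches `min_substring_freq`. Merges never cross the `.` separator or
absorb special tokens, so merged tokens are always molecular
substructures. Two open choices were resolved as follows: ties between
equally frequent pairs break lexicographically (making learning
deterministic; the original pair-encoding description is silent), and the
frequency threshold applies at merge *formation* time (the alternative —
thresholding final substring counts — is noted but not implemented; at
formation time the rule doubles as the stopping criterion). The canonical
threshold for full-scale corpora is 2000 occurrences; at desk scale it is
a free parameter and tests use values scaled to their corpus sizes.

# Embeddings

`train_embeddings()` is skip-gram with negative sampling (window 5,
dimension 256 at full scale; desk tests use smaller dimensions), trained
on a corpus of single molecules — every reactant, reagent and product
contributes one sequence, with no `.` separators. Skip-gram was chosen
over CBOW as the common default for small corpora; the architecture and
settings are recorded in the table's metadata. Special tokens get zero
vectors (they never occur inside single molecules), and the translator
refuses a frozen table that does not cover its vocabulary. Training is
single-threaded with a private seeded generator, so results are
bit-reproducible. Epochs and negative-sample counts are defaults recorded
in metadata, not asserted by tests.

# The translator

The harness is a minimal in-repo encoder–decoder transformer
(RcppArmadillo): pre-LayerNorm blocks, sinusoidal positions, multi-head
scaled dot-product attention, ReLU feed-forward, Adam with gradient
clipping, and beam-search n-best decoding (beam size 10). Pre-LN was
chosen because it trains stably under a constant learning rate, avoiding
warm-up schedules at desk scale; gradients are verified against finite
differences in the test suite. Sequences are packed row-wise so
projections and feed-forward layers run as single large GEMMs per batch.

Two presets: `"paper"` mirrors the full-scale shape (4 layers, embedding
256, feed-forward 2048, 8 heads, 4096-token batches, validation every
10000 steps × augmentation factor); `"desk"` (2 layers, embedding 64,
feed-forward 256, 4 heads, 1024-token batches, validation every 200 steps
× augmentation factor) trains the synthetic tasks on one CPU in minutes.
Early stopping follows the contract: training stops when *neither*
validation token accuracy *nor* perplexity has improved for `patience`
(10) consecutive validations, and the best validated parameters are
retained. Candidates that fail to detokenize into valid chemistry are
kept as raw strings; the metrics layer scores them as invalid.

Problem sizes used by the acceptance suite (the package's own choices):
the end-to-end check generates 5000 reactions (85/6.25/8.75% split),
trains desk-preset forward and retro models for up to 2200 steps each,
and evaluates beam-10 n-best lists on the ~440 test reactions; the
copy-task oracle trains on 1700 of 2000 distinct library molecules for up
to 5000 steps and requires ≥ 99% held-out exact-sequence accuracy.

# Evaluation

* **Strict hit**: canonical molecule *set* equality — every target
  molecule predicted and nothing extra; any unparseable molecule in a
  candidate makes it a miss. Set (not multiset) comparison follows the
  standard definition; duplicated predictions neither help nor hurt.
* **Lenient hit**: at least one shared canonical molecule; unparseable
  candidate molecules are dropped individually and tallied in the
  invalid-candidate rate.
* **Top-k accuracy**: fraction of records with a hit in the first k
  candidates. Beam output is taken at face value — no deduplication of
  canonically identical candidates across ranks (no published rule
  exists; raw ranks are reported).
* **Round-trip accuracy**: rank-1 predicted reactants (plus the true
  reagents when the scenario includes them) are fed to the matched
  forward model; success iff its rank-1 product strictly matches the true
  product. Matching compares products only, not reagents echoed in the
  source. With the template-oracle forward model, any valid precursor set
  under the template succeeds — which is exactly why round-trip accuracy
  bounds strict top-1 from above on synthetic data.
* **P/R/F at rank k**: over the set of N unique canonical molecules
  pooled from the top-k candidates, with T matching any of the M unique
  target molecules: P = T/N, R = T/M, F = 2PR/(P+R), with P = 0 when
  N = 0 and F = 0 when P + R = 0. Unparseable molecules are excluded from
  N and counted as invalid.
* **Binned analysis**: records are binned by their number of target
  reagents; bins beyond 12 reagents or with fewer than `min_bin_n`
  records (default 20; sparse-bin discarding needs *some* threshold and
  none is published) are excluded; pooled scores weight bin means by bin
  record counts, which provably equals direct pooling over the retained
  records.
* **Agreement tabulation**: two expert groups each label every selected
  reaction wrong / semi-correct / correct; "not wrong" = semi-correct or
  correct, "contradictory" = one group not-wrong and the other wrong. The
  three categories partition the label set; exact fractions and rounded
  integer percentages are both reported. Per-group rates are computed,
  but the published per-group contingency tables are not reconstructible
  from aggregate counts, so only the joint categories are used in
  acceptance checks.

# Numerical and interface choices

* Errors are classed conditions (`rxn_invalid_molecule`,
  `rxn_config_error`, `rxn_undefined_metric`, `rxn_coverage_error`, ...)
  so callers can react programmatically; empty metric inputs raise
  undefined-metric errors rather than returning NaN.
* Dataset splitting uses largest-remainder rounding, so the three parts
  partition any n exactly.
* Canonicalization results are memoised per session; metric computations
  over thousands of records re-canonicalize each distinct string once.
* All randomness is seed-controlled: generation and augmentation through
  a save/restore of R's RNG state, C++ components through private
  mt19937 generators; fixed seeds reproduce results bit-for-bit.
* The command-line surface is intentionally the R API plus
  `scripts/acceptance.R`; the package's functions and this vignette are
  the interface.

# Known limitations

* The SMILES subset has no stereochemistry and no aromaticity
  perception; canonical identity is within-convention only.
* The SELFIES dialect covers B/C/N/O/P/S and halogens without aromatic
  tokens; its index alphabet and branch semantics are this package's own
  (documented) convention, not byte-compatible with other encoders.
* The transformer is a minimal implementation: no dropout, label
  smoothing, or learning-rate schedules; it is sized for desk-scale
  experiments, and full-scale accuracy tables from GPU-scale training are
  out of scope.
* Synthetic reactions are structurally, not chemically, realistic;
  quantitative results on them say nothing about accuracy on real
  reaction corpora.
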