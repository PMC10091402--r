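# Template-based synthetic reaction datasets.
#
# Reactions are built by string-level fragment grafting over a curated
# library of valid SMILES fragments: every fragment starts and ends on an
# atom with a free valence, so concatenating fragments, functional-group
# suffixes and linkers always yields a parseable molecule. Each template
# carries a slot signature of functional groups; a reactant for a slot is
# `fragment + group`, and the product is the fragments interleaved with the
# template's linker strings. The chemistry is deliberately schematic — what
# is emulated is the statistical and structural shape of a large curated
# reaction corpus: 1-5 reactants per reaction (median 2, mean 1.78, sd
# 0.47), 0-21 reagents (median 3, mean 3.03, sd 2.22), and a product that
# is recoverable from its reactants by a known deterministic transform.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Graftable fragment alphabet: valid standalone molecules whose first and
# last written atoms both have a free valence. Two aromatic (lowercase)
# fragments are included on purpose: they are valid SMILES but outside the
# SELFIES-encodable dialect, exercising the "?" fallback path the way rare
# unencodable molecules do in real corpora.
.rxn_fragments <- c(
  "C", "CC", "CCC", "CCCC", "CCCCC", "CC(C)C", "CC(C)(C)C",
  "C=CC", "CC=CC", "CCOC", "CCOCC", "CN(C)C", "CCSC", "CC(F)C",
  "CC(Cl)C", "C1CCCCC1", "C1CCCC1", "C1CCOC1",
  "C1=CC=CC=C1", "CC1=CC=CC=C1", "c1ccccc1", "c1ccncc1"
)

# Reagent molecules characteristic of no reactant form (checked at library
# build time): solvents, bases, catalysts, salts.
.rxn_global_reagents <- c(
  "O", "ClCCl", "ClC(Cl)Cl", "CS(C)=O", "CN(C)C=O", "C1COCCO1",
  "CCN(CC)CC", "CC#N", "OS(=O)(=O)O", "Cl", "Br", "B",
  "[Na+]", "[K+]", "[Li+]", "[Cl-]", "[Br-]", "[OH-]",
  "[Pd]", "[Ni]", "[Mg+2]", "O=C([O-])[O-]", "[O-]S(=O)(=O)[O-]"
)

.rxn_template_defs <- list(
  list(id = "ketone_reduction",      groups = "C(=O)C",                          links = "C(O)C",
       weight = 0.1225, pool = c("[Na+]", "[Li+]", "B", "C1CCOC1", "O")),
  list(id = "alkene_hydrogenation",  groups = "C=C",                             links = "CC",
       weight = 0.1225, pool = c("[Pd]", "[Ni]", "C1CCOC1", "O")),
  list(id = "esterification",        groups = c("C(=O)O", "O"),                  links = c("C(=O)O", ""),
       weight = 0.147,  pool = c("OS(=O)(=O)O", "Cl", "C1CCOC1", "ClCCl")),
  list(id = "amide_coupling",        groups = c("C(=O)O", "N"),                  links = c("C(=O)N", ""),
       weight = 0.147,  pool = c("CCN(CC)CC", "CN(C)C=O", "ClCCl", "CC#N")),
  list(id = "williamson_ether",      groups = c("Br", "O"),                      links = c("O", ""),
       weight = 0.147,  pool = c("O=C([O-])[O-]", "[K+]", "CC#N", "CN(C)C=O")),
  list(id = "n_alkylation",          groups = c("Br", "N"),                      links = c("N", ""),
       weight = 0.147,  pool = c("CCN(CC)CC", "[K+]", "O=C([O-])[O-]", "CC#N")),
  list(id = "suzuki_coupling",       groups = c("Br", "B(O)O"),                  links = c("", ""),
       weight = 0.147,  pool = c("[Pd]", "O=C([O-])[O-]", "[K+]", "C1COCCO1", "O")),
  list(id = "ester_amine_cascade",   groups = c("C(=O)O", "O", "N"),             links = c("C(=O)O", "N", ""),
       weight = 0.018,  pool = c("CCN(CC)CC", "ClCCl", "CN(C)C=O")),
  list(id = "tetra_assembly",        groups = c("C(=O)O", "O", "N", "S"),        links = c("C(=O)O", "N", "S", ""),
       weight = 0.0015, pool = c("CCN(CC)CC", "O", "ClCCl")),
  list(id = "penta_assembly",        groups = c("C(=O)O", "O", "N", "S", "Br"),  links = c("C(=O)O", "N", "S", "O", ""),
       weight = 0.0005, pool = c("CCN(CC)CC", "O", "[Pd]", "C1COCCO1"))
)

.template_env <- new.env(parent = emptyenv())

#' The built-in reaction template library
#'
#' Builds (once per session) the template library: for each template, the
#' per-slot admissible fragments; globally, the reactant lookup table
#' mapping the canonical form of `fragment + group` back to its
#' `(fragment, group)` pair. Canonical-form collisions between different
#' pairs are resolved at build time by excluding the colliding fragment
#' from the later slot, so the lookup — and therefore the forward
#' transform — is a well-defined pure function. Reagent pools are verified
#' to be disjoint from all reactant forms.
#'
#' @return a list with `templates`, `lookup` (environment), and `fragments`.
#' @export
reaction_template_library <- function() {
  if (!is.null(.template_env$lib)) return(.template_env$lib)
  lookup <- new.env(parent = emptyenv())
  templates <- list()
  all_groups <- unique(unlist(lapply(.rxn_template_defs, `[[`, "groups")))
  admissible <- list()
  for (g in all_groups) {
    ok <- character(0)
    for (f in .rxn_fragments) {
      r <- paste0(f, g)
      key <- canonicalize_smiles(r)
      if (is.null(lookup[[key]])) {
        lookup[[key]] <- list(frag = f, group = g)
        ok <- c(ok, f)
      }
    }
    admissible[[g]] <- ok
  }
  reactant_keys <- ls(lookup)
  for (def in .rxn_template_defs) {
    pool <- unique(c(def$pool, .rxn_global_reagents))
    pool_keys <- vapply(pool, canonicalize_smiles, character(1))
    if (any(pool_keys %in% reactant_keys))
      abort_config(sprintf("template %s: reagent pool overlaps reactant forms", def$id))
    templates[[def$id]] <- list(
      template_id = def$id,
      reactant_slots = length(def$groups),
      slot_groups = def$groups,
      links = def$links,
      weight = def$weight,
      reagent_pool = pool,
      slot_fragments = admissible[def$groups]
    )
  }
  .template_env$lib <- list(templates = templates, lookup = lookup,
                            fragments = .rxn_fragments)
  .template_env$lib
}

template_signature <- function(tpl) paste(sort(tpl$slot_groups), collapse = "|")

assemble_product <- function(tpl, frags) {
  paste0(paste0(frags, tpl$links), collapse = "")
}

#' Template-oracle forward model
#'
#' Returns a deterministic product-prediction function: the exact forward
#' transform of the synthetic template library. Given a "."-joined source
#' string, each molecule is canonicalized and looked up as a reactant form;
#' molecules that are not reactant forms (e.g., appended reagents) are
#' ignored. If the recovered functional-group multiset matches a template's
#' slot signature, the template's product is assembled and returned;
#' otherwise the empty string (scored as a miss downstream). Because any
#' valid precursor set is accepted — not just the one a test record came
#' from — round-trip scoring with this oracle credits alternative
#' synthesis routes that strict matching rejects.
#'
#' @param lib a template library, default [reaction_template_library()].
#' @return `function(source_string) -> product string`.
#' @export
template_forward_oracle <- function(lib = reaction_template_library()) {
  signatures <- vapply(lib$templates, template_signature, character(1))
  function(source) {
    mols <- split_molecules(source)
    hits <- list()
    for (m in mols) {
      key <- tryCatch(canonicalize_smiles(m), rxn_invalid_molecule = function(e) NULL)
      if (is.null(key)) next
      h <- lib$lookup[[key]]
      if (!is.null(h)) hits[[length(hits) + 1L]] <- h
    }
    if (length(hits) == 0L) return("")
    sig <- paste(sort(vapply(hits, `[[`, character(1), "group")), collapse = "|")
    i <- match(sig, signatures)
    if (is.na(i)) return("")
    tpl <- lib$templates[[i]]
    frags <- character(tpl$reactant_slots)
    used <- logical(length(hits))
    for (s in seq_along(tpl$slot_groups)) {
      j <- which(!used & vapply(hits, `[[`, character(1), "group") == tpl$slot_groups[s])[1]
      frags[s] <- hits[[j]]$frag
      used[j] <- TRUE
    }
    assemble_product(tpl, frags)
  }
}

#' Synthetic dataset configuration
#'
#' @param n_reactions number of reactions to generate.
#' @param seed integer seed; generation is bit-identical per seed.
#' @param split_fractions train/valid/test fractions summing to 1.
#' @param reagent_mu,reagent_sd target mean and sd of the reagent-count
#'   distribution (defaults match the corpus statistics emulated: mean 3.03,
#'   sd 2.22, median 3); realised as a negative binomial truncated at
#'   `reagent_max`.
#' @param reagent_max upper truncation of reagent counts (21).
#' @param multi_product if `TRUE`, condensation-style templates also emit
#'   water as a second product; defaults to single-product records.
#' @return a list of class `rxn_synthetic_config`.
#' @export
synthetic_config <- function(n_reactions, seed = 1L,
                             split_fractions = c(0.85, 0.0625, 0.0875),
                             reagent_mu = 3.03, reagent_sd = 2.22,
                             reagent_max = 21L, multi_product = FALSE) {
  if (n_reactions < 0) abort_config("n_reactions must be >= 0")
  if (length(split_fractions) != 3L || any(split_fractions < 0) ||
      abs(sum(split_fractions) - 1) > 1e-9)
    abort_config("split_fractions must be three non-negative numbers summing to 1")
  v <- reagent_sd^2
  if (v <= reagent_mu) abort_config("reagent_sd^2 must exceed reagent_mu (overdispersion)")
  structure(
    list(n_reactions = as.integer(n_reactions), seed = as.integer(seed),
         split_fractions = split_fractions,
         reagent_mu = reagent_mu, reagent_size = reagent_mu^2 / (v - reagent_mu),
         reagent_max = as.integer(reagent_max), multi_product = multi_product),
    class = "rxn_synthetic_config"
  )
}

sample_reagent_count <- function(n, config) {
  x <- stats::rnbinom(n, size = config$reagent_size, mu = config$reagent_mu)
  while (any(x > config$reagent_max)) {
    i <- x > config$reagent_max
    x[i] <- stats::rnbinom(sum(i), size = config$reagent_size, mu = config$reagent_mu)
  }
  x
}

.condensation_templates <- c("esterification", "amide_coupling", "ester_amine_cascade",
                             "tetra_assembly", "penta_assembly")

#' Generate a synthetic reaction dataset
#'
#' Draws `config$n_reactions` reactions: a template (by weight, realizing
#' the reactant-count distribution), distinct admissible fragments for its
#' slots, reagents from the template's pool with a truncated
#' negative-binomial count, and the product assembled by the template
#' transform — so a perfect forward predictor exists by construction.
#'
#' @param config a [synthetic_config()].
#' @param lib template library.
#' @return a tibble with list-columns `reactants`, `reagents`, `products`
#'   and a `template_id` column; one row per reaction.
#' @export
generate_reactions <- function(config, lib = reaction_template_library()) {
  stopifnot(inherits(config, "rxn_synthetic_config"))
  templates <- lib$templates
  if (length(templates) == 0L) abort_config("template library is empty")
  n <- config$n_reactions
  if (n == 0L)
    return(tibble::tibble(reactants = list(), reagents = list(),
                          products = list(), template_id = character(0)))
  with_seed(config$seed, {
    weights <- vapply(templates, `[[`, numeric(1), "weight")
    tpl_idx <- sample.int(length(templates), n, replace = TRUE, prob = weights)
    n_reag <- sample_reagent_count(n, config)
    reactants <- vector("list", n); reagents <- vector("list", n)
    products <- vector("list", n)
    for (i in seq_len(n)) {
      tpl <- templates[[tpl_idx[i]]]
      frags <- character(tpl$reactant_slots)
      taken <- character(0)
      for (s in seq_len(tpl$reactant_slots)) {
        cand <- setdiff(tpl$slot_fragments[[s]], taken)
        if (length(cand) == 0L) cand <- tpl$slot_fragments[[s]]
        frags[s] <- cand[sample.int(length(cand), 1L)]
        taken <- c(taken, frags[s])
      }
      reactants[[i]] <- paste0(frags, tpl$slot_groups)
      k <- min(n_reag[i], length(tpl$reagent_pool))
      reagents[[i]] <- if (k > 0L) sample(tpl$reagent_pool, k) else character(0)
      prod <- assemble_product(tpl, frags)
      products[[i]] <-
        if (config$multi_product && tpl$template_id %in% .condensation_templates)
          c(prod, "O") else prod
    }
    tibble::tibble(reactants = reactants, reagents = reagents,
                   products = products,
                   template_id = names(templates)[tpl_idx])
  })
}

#' Split a dataset into train/valid/test partitions
#'
#' Sizes are the largest-remainder rounding of `fractions * nrow(records)`,
#' so the three parts always partition the records exactly; the assignment
#' is a seeded random permutation.
#'
#' @param records a reaction tibble (or any data frame).
#' @param fractions three fractions summing to 1.
#' @param seed integer seed.
#' @return a named list `train`, `valid`, `test`.
#' @export
split_dataset <- function(records, fractions = c(0.85, 0.0625, 0.0875), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9)
    abort_config("split fractions must sum to 1")
  n <- nrow(records)
  exact <- n * fractions
  sizes <- floor(exact)
  short <- n - sum(sizes)
  if (short > 0) {
    order_rem <- order(exact - sizes, decreasing = TRUE)
    sizes[order_rem[seq_len(short)]] <- sizes[order_rem[seq_len(short)]] + 1L
  }
  perm <- with_seed(seed, sample.int(n))
  idx <- split(perm, rep(c("train", "valid", "test"), times = sizes))
  list(train = records[sort(idx$train), , drop = FALSE],
       valid = records[sort(idx$valid), , drop = FALSE],
       test = records[sort(idx$test), , drop = FALSE])
}

#' Build (source, target) task samples from reaction records
#'
#' Product prediction: source = reactants (plus reagents when
#' `include_reagents`), target = products. Reactant prediction: source =
#' products (plus reagents), target = reactants. Reagent prediction:
#' source = reactants plus products, target = reagents. Molecules within a
#' field are joined with the "." separator; no special token distinguishes
#' reactants from reagents. Records with zero reagents are skipped for the
#' reagent task (their indices are returned in attribute `"skipped"`).
#'
#' @param records a reaction tibble from [generate_reactions()].
#' @param task `"product"`, `"reactant"` or `"reagent"`.
#' @param include_reagents include reagents on the source side.
#' @return a tibble with `source`, `target`, plus carried-through metadata
#'   columns `reagents` and `products` (list-columns) used by round-trip
#'   and binned evaluation.
#' @export
build_task_samples <- function(records, task = c("product", "reactant", "reagent"),
                               include_reagents = FALSE) {
  task <- match.arg(task)
  n <- nrow(records)
  src <- character(n); tgt <- character(n)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    rct <- records$reactants[[i]]; rgt <- records$reagents[[i]]
    prd <- records$products[[i]]
    if (task == "product") {
      src[i] <- join_molecules(c(rct, if (include_reagents) rgt))
      tgt[i] <- join_molecules(prd)
    } else if (task == "reactant") {
      src[i] <- join_molecules(c(prd, if (include_reagents) rgt))
      tgt[i] <- join_molecules(rct)
    } else {
      if (length(rgt) == 0L) { keep[i] <- FALSE; next }
      src[i] <- join_molecules(c(rct, prd))
      tgt[i] <- join_molecules(rgt)
    }
  }
  out <- tibble::tibble(
    source = src[keep], target = tgt[keep],
    reagents = records$reagents[keep], products = records$products[keep]
  )
  attr(out, "skipped") <- which(!keep)
  out
}

#' Majority-class baseline accuracy
#'
#' The accuracy of always predicting the most frequent target string: the
#' floor any sequence model must beat.
#'
#' @param targets character vector of target strings.
#' @return a fraction in (0, 1].
#' @export
majority_baseline <- function(targets) {
  if (length(targets) == 0L) abort_undefined_metric("no targets")
  max(table(targets)) / length(targets)
}

#' Read and write reaction-SMILES text files
#'
#' One reaction per line, `reactants>reagents>products`, with molecules
#' "."-joined within each field.
#'
#' @param records a reaction tibble.
#' @param path file path.
#' @return `write_reaction_smiles()`: the path, invisibly;
#'   `read_reaction_smiles()`: a reaction tibble.
#' @export
write_reaction_smiles <- function(records, path) {
  lines <- vapply(seq_len(nrow(records)), function(i) {
    paste(join_molecules(records$reactants[[i]]),
          join_molecules(records$reagents[[i]]),
          join_molecules(records$products[[i]]), sep = ">")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_reaction_smiles
#' @export
read_reaction_smiles <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, ">", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) abort_rxn(sprintf("line %d is not 'reactants>reagents>products'",
                                  which(bad)[1]), class = "rxn_parse_error")
  tibble::tibble(
    reactants = lapply(parts, function(p) split_molecules(p[1])),
    reagents = lapply(parts, function(p) split_molecules(p[2])),
    products = lapply(parts, function(p) split_molecules(p[3])),
    template_id = NA_character_
  )
}
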