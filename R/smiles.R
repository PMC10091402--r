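# Molecule-string services over a molecular-graph representation of SMILES.
#
# The supported dialect covers the organic subset (B, C, N, O, P, S, F, Cl,
# Br, I), aromatic lowercase atoms, bracket atoms with isotope / explicit H /
# charge, bond orders -, =, #, :, branches, and ring closures (1-9 and %nn).
# Stereo descriptors are not modelled: '/' and '\' are read as single bonds
# and '@' is ignored inside brackets. Aromatic and Kekule forms are treated
# as distinct molecules (no aromaticity perception); all strings produced by
# the synthetic-reaction generator use one consistent convention, so string
# canonicalization is a faithful molecule identity within the pipeline.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_BARE <- c("b", "c", "n", "o", "p", "s")

#' Parse a SMILES string into a molecular graph
#'
#' @param s a single SMILES string for one connected molecule (no ".").
#' @return a list with `atoms` (data.frame: `elem`, `arom`, `charge`,
#'   `hcount` — `NA` means implicit, `iso`) and `bonds` (data.frame: `a1`,
#'   `a2`, `order` with aromatic bonds encoded as 1.5).
#' @keywords internal
smiles_parse <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s))
    abort_invalid_molecule(if (is.character(s) && length(s) == 1 && !is.na(s)) s else "",
                           "empty or non-string input")

  n_chars <- nchar(s)
  elem <- character(0); arom <- logical(0); charge <- integer(0)
  hcount <- integer(0); iso <- integer(0)
  b1 <- integer(0); b2 <- integer(0); bord <- numeric(0)

  prev <- NA_integer_        # atom awaiting the next bond
  stack <- integer(0)        # branch return points
  pend <- NA_real_           # explicit bond symbol not yet consumed
  rings <- list()            # open ring closures: digit -> list(atom, order)

  add_atom <- function(e, ar, ch, hc, is) {
    elem[length(elem) + 1L] <<- e
    arom[length(arom) + 1L] <<- ar
    charge[length(charge) + 1L] <<- ch
    hcount[length(hcount) + 1L] <<- hc
    iso[length(iso) + 1L] <<- is
    length(elem)
  }
  add_bond <- function(a, b, o) {
    b1[length(b1) + 1L] <<- a; b2[length(b2) + 1L] <<- b
    bord[length(bord) + 1L] <<- o
  }
  bond_default <- function(a, b) if (arom[a] && arom[b]) 1.5 else 1

  i <- 1L
  while (i <= n_chars) {
    ch <- substr(s, i, i)
    if (ch == "[") {
      close <- regexpr("]", substr(s, i, n_chars), fixed = TRUE)
      if (close < 0) abort_invalid_molecule(s, "unclosed bracket atom")
      body <- substr(s, i + 1L, i + close - 2L)
      m <- regmatches(body,
        regexec("^(\\d+)?([A-Za-z][a-z]?)(@+)?(H(\\d+)?)?([+-]\\d+|\\++|-+)?$", body))[[1]]
      if (length(m) == 0L) abort_invalid_molecule(s, sprintf("bad bracket atom [%s]", body))
      sym <- m[3]
      ar <- substr(sym, 1, 1) %in% letters
      e <- if (ar) paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, nchar(sym))) else sym
      hc <- if (m[5] == "") 0L else if (m[6] == "") 1L else as.integer(m[6])
      chg <- 0L
      if (m[7] != "") {
        cs <- m[7]
        chg <- if (grepl("^[+-]\\d+$", cs)) {
          as.integer(cs)
        } else {
          (if (substr(cs, 1, 1) == "+") 1L else -1L) * nchar(cs)
        }
      }
      is <- if (m[2] == "") NA_integer_ else as.integer(m[2])
      a <- add_atom(e, ar, chg, hc, is)
      if (!is.na(prev)) add_bond(prev, a, if (is.na(pend)) bond_default(prev, a) else pend)
      prev <- a; pend <- NA_real_
      i <- i + close
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      two <- substr(s, i, i + 1L)
      e <- if (two %in% c("Cl", "Br")) two else ch
      a <- add_atom(e, FALSE, 0L, NA_integer_, NA_integer_)
      if (!is.na(prev)) add_bond(prev, a, if (is.na(pend)) bond_default(prev, a) else pend)
      prev <- a; pend <- NA_real_
      i <- i + nchar(e)
    } else if (ch %in% AROMATIC_BARE) {
      a <- add_atom(toupper(ch), TRUE, 0L, NA_integer_, NA_integer_)
      if (!is.na(prev)) add_bond(prev, a, if (is.na(pend)) bond_default(prev, a) else pend)
      prev <- a; pend <- NA_real_
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pend <- switch(ch, "-" = 1, "=" = 2, "#" = 3, ":" = 1.5, "/" = 1, "\\" = 1)
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) abort_invalid_molecule(s, "branch with no preceding atom")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) abort_invalid_molecule(s, "unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch) || ch == "%") {
      if (ch == "%") {
        key <- substr(s, i + 1L, i + 2L)
        if (!grepl("^[0-9]{2}$", key)) abort_invalid_molecule(s, "bad %nn ring closure")
        i <- i + 3L
      } else {
        key <- ch
        i <- i + 1L
      }
      if (is.na(prev)) abort_invalid_molecule(s, "ring closure with no preceding atom")
      if (!is.null(rings[[key]])) {
        op <- rings[[key]]
        if (op$atom == prev) abort_invalid_molecule(s, "self ring closure")
        o <- if (!is.na(pend)) pend else if (!is.na(op$order)) op$order else bond_default(op$atom, prev)
        add_bond(op$atom, prev, o)
        rings[[key]] <- NULL
      } else {
        rings[[key]] <- list(atom = prev, order = pend)
      }
      pend <- NA_real_
    } else {
      abort_invalid_molecule(s, sprintf("unexpected character '%s' at position %d", ch, i))
    }
  }
  if (length(rings) > 0L) abort_invalid_molecule(s, "unmatched ring bonds")
  if (length(stack) > 0L) abort_invalid_molecule(s, "unmatched '('")
  if (!is.na(pend)) abort_invalid_molecule(s, "dangling bond symbol")
  if (length(elem) == 0L) abort_invalid_molecule(s, "no atoms")

  g <- list(
    atoms = data.frame(elem = elem, arom = arom, charge = charge,
                       hcount = hcount, iso = iso, stringsAsFactors = FALSE),
    bonds = data.frame(a1 = b1, a2 = b2, order = bord)
  )
  if (!smiles_connected(g)) abort_invalid_molecule(s, "disconnected components (use '.'-separated lists)")
  g
}

smiles_connected <- function(g) {
  n <- nrow(g$atoms)
  if (n == 1L) return(TRUE)
  adj <- smiles_adjacency(g)
  seen <- logical(n); seen[1L] <- TRUE; frontier <- 1L
  while (length(frontier) > 0L) {
    nxt <- unique(unlist(lapply(frontier, function(a) adj[[a]]$nbr)))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

smiles_adjacency <- function(g) {
  n <- nrow(g$atoms)
  adj <- rep(list(list(nbr = integer(0), bond = integer(0))), n)
  if (nrow(g$bonds) > 0L) {
    for (k in seq_len(nrow(g$bonds))) {
      a <- g$bonds$a1[k]; b <- g$bonds$a2[k]
      adj[[a]]$nbr <- c(adj[[a]]$nbr, b); adj[[a]]$bond <- c(adj[[a]]$bond, k)
      adj[[b]]$nbr <- c(adj[[b]]$nbr, a); adj[[b]]$bond <- c(adj[[b]]$bond, k)
    }
  }
  adj
}

smiles_atom_string <- function(g, a) {
  at <- g$atoms[a, ]
  bare <- at$elem %in% ORGANIC_SUBSET && at$charge == 0L &&
    is.na(at$hcount) && is.na(at$iso)
  sym <- if (at$arom) paste0(tolower(substr(at$elem, 1, 1)), substr(at$elem, 2, nchar(at$elem))) else at$elem
  if (bare) return(sym)
  hc <- if (is.na(at$hcount) || at$hcount == 0L) "" else if (at$hcount == 1L) "H" else paste0("H", at$hcount)
  chg <- if (at$charge == 0L) "" else if (at$charge == 1L) "+" else if (at$charge == -1L) "-"
    else sprintf("%+d", at$charge)
  iss <- if (is.na(at$iso)) "" else as.character(at$iso)
  paste0("[", iss, sym, hc, chg, "]")
}

smiles_bond_string <- function(g, k) {
  o <- g$bonds$order[k]
  a <- g$bonds$a1[k]; b <- g$bonds$a2[k]
  both_arom <- g$atoms$arom[a] && g$atoms$arom[b]
  if (o == 1) { if (both_arom) "-" else "" }
  else if (o == 1.5) { if (both_arom) "" else ":" }
  else if (o == 2) "="
  else if (o == 3) "#"
  else abort_invalid_molecule("", sprintf("unwritable bond order %s", o))
}

#' Write a molecular graph as a SMILES string
#'
#' Depth-first traversal from `root`, visiting neighbours in increasing
#' `ranks` order. Different `root`/`ranks` choices yield different surface
#' strings for the same molecule.
#' @keywords internal
smiles_write <- function(g, root = 1L, ranks = seq_len(nrow(g$atoms))) {
  n <- nrow(g$atoms)
  adj <- smiles_adjacency(g)
  visited <- logical(n)
  bond_used <- logical(nrow(g$bonds))
  order_of <- integer(n)  # preorder position
  children <- rep(list(integer(0)), n)   # bond indices, in visit order
  ring_at <- rep(list(integer(0)), n)    # ring bond indices noted at each atom
  counter <- 0L

  # Pass 1: classify bonds as tree or ring, fix visit order.
  walk <- function(u) {
    visited[u] <<- TRUE
    counter <<- counter + 1L
    order_of[u] <<- counter
    nbrs <- adj[[u]]$nbr; bnds <- adj[[u]]$bond
    ord <- order(ranks[nbrs])
    for (j in ord) {
      v <- nbrs[j]; k <- bnds[j]
      if (bond_used[k]) next
      if (visited[v]) {
        bond_used[k] <<- TRUE
        ring_at[[u]] <<- c(ring_at[[u]], k)
        ring_at[[v]] <<- c(ring_at[[v]], k)
      } else {
        bond_used[k] <<- TRUE
        children[[u]] <<- c(children[[u]], k)
        walk(v)
      }
    }
  }
  walk(root)
  if (!all(visited)) abort_invalid_molecule("", "disconnected graph in writer")

  # Assign ring-closure digits in emission order, reusing freed digits.
  ring_digit <- integer(nrow(g$bonds))
  in_use <- logical(0)
  emit_order <- order(order_of)
  for (u in emit_order) {
    for (k in ring_at[[u]]) {
      other <- if (g$bonds$a1[k] == u) g$bonds$a2[k] else g$bonds$a1[k]
      if (order_of[other] > order_of[u]) {          # opening here
        d <- which(!c(in_use, FALSE))[1]
        if (d > length(in_use)) in_use <- c(in_use, TRUE) else in_use[d] <- TRUE
        ring_digit[k] <- d
      } else {                                      # closing here
        in_use[ring_digit[k]] <- FALSE
      }
    }
  }
  digit_str <- function(d) if (d < 10) as.character(d) else sprintf("%%%02d", d)

  emit <- function(u) {
    out <- smiles_atom_string(g, u)
    for (k in ring_at[[u]]) {
      other <- if (g$bonds$a1[k] == u) g$bonds$a2[k] else g$bonds$a1[k]
      # bond symbol printed at the opening endpoint only
      bs <- if (order_of[other] > order_of[u]) smiles_bond_string(g, k) else ""
      out <- paste0(out, bs, digit_str(ring_digit[k]))
    }
    kids <- children[[u]]
    nk <- length(kids)
    for (j in seq_along(kids)) {
      k <- kids[j]
      v <- if (g$bonds$a1[k] == u) g$bonds$a2[k] else g$bonds$a1[k]
      piece <- paste0(smiles_bond_string(g, k), emit(v))
      out <- if (j < nk) paste0(out, "(", piece, ")") else paste0(out, piece)
    }
    out
  }
  emit(root)
}

# --- canonical labelling -----------------------------------------------------

smiles_initial_ranks <- function(g) {
  n <- nrow(g$atoms)
  deg <- integer(n); bsum <- numeric(n)
  if (nrow(g$bonds) > 0L) {
    tab <- tabulate(c(g$bonds$a1, g$bonds$a2), nbins = n)
    deg <- tab
    for (k in seq_len(nrow(g$bonds))) {
      bsum[g$bonds$a1[k]] <- bsum[g$bonds$a1[k]] + g$bonds$order[k]
      bsum[g$bonds$a2[k]] <- bsum[g$bonds$a2[k]] + g$bonds$order[k]
    }
  }
  key <- sprintf("%s|%d|%+03d|%03d|%03d|%d|%04.1f",
                 g$atoms$elem, as.integer(g$atoms$arom), g$atoms$charge,
                 ifelse(is.na(g$atoms$hcount), 999L, g$atoms$hcount),
                 ifelse(is.na(g$atoms$iso), 0L, g$atoms$iso), deg, bsum)
  match(key, sort(unique(key)))
}

smiles_refine_ranks <- function(g, ranks) {
  adj <- smiles_adjacency(g)
  n <- length(ranks)
  repeat {
    key <- vapply(seq_len(n), function(a) {
      nb <- adj[[a]]$nbr
      if (length(nb) == 0L) return(sprintf("%06d|", ranks[a]))
      sig <- sort(sprintf("%04.1f:%06d", g$bonds$order[adj[[a]]$bond], ranks[nb]))
      sprintf("%06d|%s", ranks[a], paste(sig, collapse = ","))
    }, character(1))
    new <- match(key, sort(unique(key)))
    if (max(new) == max(ranks)) return(new)
    ranks <- new
  }
}

smiles_canonical <- function(g) {
  rec <- function(ranks) {
    ranks <- smiles_refine_ranks(g, ranks)
    n <- length(ranks)
    if (max(ranks) == n) {
      return(smiles_write(g, root = which(ranks == 1L), ranks = ranks))
    }
    tied <- min(ranks[duplicated(ranks) | duplicated(ranks, fromLast = TRUE)])
    best <- NULL
    for (a in which(ranks == tied)) {
      r2 <- ranks * 2L
      r2[a] <- r2[a] - 1L
      cand <- rec(r2)
      if (is.null(best) || cand < best) best <- cand
    }
    best
  }
  rec(smiles_initial_ranks(g))
}

.canon_cache <- new.env(parent = emptyenv())

#' Canonicalize a SMILES string
#'
#' Maps every surface string of a molecule to a unique normal form so that
#' string equality can stand in for molecule equality. Idempotent; results
#' are memoised per session.
#'
#' @param s a SMILES string (one molecule; no ".").
#' @return the canonical SMILES string.
#' @examples
#' canonicalize_smiles("C(O)C") == canonicalize_smiles("OCC")
#' @export
canonicalize_smiles <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s))
    abort_invalid_molecule("", "empty or non-string input")
  hit <- .canon_cache[[s]]
  if (!is.null(hit)) return(hit)
  out <- smiles_canonical(smiles_parse(s))
  .canon_cache[[s]] <- out
  # a canonical string canonicalizes to itself by construction; cache it too
  .canon_cache[[out]] <- out
  out
}

#' Test whether a string parses as a single valid molecule
#' @param s a candidate SMILES string.
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_smiles <- function(s) {
  !inherits(tryCatch(smiles_parse(s), rxn_invalid_molecule = function(e) e),
            "rxn_invalid_molecule")
}

#' Random non-canonical SMILES enumeration
#'
#' Re-serializes a molecule from a uniformly random root atom with a random
#' neighbour visit order, producing one of the molecule's many valid surface
#' strings. The encoded molecule is unchanged: the canonical form of the
#' output always equals the canonical form of the input. Uses R's RNG;
#' seed with [set.seed()] for reproducibility.
#'
#' @param s a SMILES string.
#' @return a SMILES string for the same molecule.
#' @export
randomize_smiles <- function(s) {
  g <- smiles_parse(s)
  n <- nrow(g$atoms)
  if (n == 1L) return(smiles_write(g))
  smiles_write(g, root = sample.int(n, 1L), ranks = sample.int(n))
}

#' Join or split "."-separated molecule lists
#'
#' Multi-molecule fields (reactant sets, reagent sets) are stored as
#' character vectors and joined with the "." separator only at
#' serialization time.
#'
#' @param mols character vector of molecule strings.
#' @return `join_molecules()`: a single string; `split_molecules()`: a
#'   character vector (empty for the empty string).
#' @export
join_molecules <- function(mols) paste(mols, collapse = ".")

#' @rdname join_molecules
#' @param s a "."-joined molecule string.
#' @export
split_molecules <- function(s) {
  if (is.na(s) || !nzchar(s)) return(character(0))
  strsplit(s, ".", fixed = TRUE)[[1]]
}
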