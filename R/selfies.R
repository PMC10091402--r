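# SELFIES-style robust molecule strings.
#
# A self-referencing bracket-token notation in which every syntactically
# well-formed token string decodes to a valid molecule: bonds exceeding an
# atom's remaining valence are truncated, and branch/ring symbols lacking
# the context they need are skipped. The dialect implemented here covers
# non-aromatic molecules over B, C, N, O, P, S, F, Cl, Br, I with charges
# and explicit hydrogen counts; aromatic (lowercase) SMILES, isotopes, and
# other elements are not encodable and fall back to the single token "?",
# mirroring the handling of rare unencodable molecules in reaction corpora.

SELFIES_FALLBACK <- "?"

.selfies_valence <- c(B = 3, C = 4, N = 3, O = 2, P = 5, S = 6,
                      F = 1, Cl = 1, Br = 1, I = 1)

# 16-symbol index alphabet: the numeric value of overloaded symbols used to
# spell branch lengths and ring distances (base 16, big-endian).
.selfies_index_alphabet <- c(
  "[C]", "[Ring1]", "[Ring2]", "[Branch1]", "[=Branch1]", "[#Branch1]",
  "[Branch2]", "[=Branch2]", "[#Branch2]", "[O]", "[N]", "[=N]",
  "[=C]", "[#C]", "[S]", "[P]"
)

selfies_atom_valence <- function(elem, charge) {
  base <- .selfies_valence[[elem]]
  v <- if (elem == "C") base - abs(charge) else base + charge
  max(v, 0)
}

selfies_index_value <- function(tok) {
  i <- match(tok, .selfies_index_alphabet)
  if (is.na(i)) 0L else i - 1L
}

selfies_spell_index <- function(q, n_symbols) {
  out <- character(n_symbols)
  for (j in seq_len(n_symbols)) {
    out[n_symbols - j + 1L] <- .selfies_index_alphabet[(q %% 16L) + 1L]
    q <- q %/% 16L
  }
  out
}

selfies_bond_prefix <- function(order) switch(as.character(order), "1" = "", "2" = "=", "3" = "#")

#' Split a SELFIES string into bracket tokens
#' @param s a SELFIES token string.
#' @return character vector of `[...]` tokens (plus "." / "?" if present).
#' @export
selfies_tokenize <- function(s) {
  if (!nzchar(s)) return(character(0))
  m <- gregexpr("\\[[^][]*\\]|\\.|\\?", s)[[1]]
  toks <- regmatches(s, gregexpr("\\[[^][]*\\]|\\.|\\?", s))[[1]]
  if (paste(toks, collapse = "") != s)
    abort_rxn(sprintf("malformed SELFIES string: %s", substr(s, 1, 60)),
              class = "rxn_tokenization_error")
  toks
}

selfies_parse_atom_token <- function(tok) {
  body <- substr(tok, 2, nchar(tok) - 1L)
  m <- regmatches(body, regexec("^(=|#)?([A-Z][a-z]?)(H(\\d+))?([+-]\\d+)?$", body))[[1]]
  if (length(m) == 0L || !(m[3] %in% names(.selfies_valence))) return(NULL)
  list(
    order = if (m[2] == "") 1L else if (m[2] == "=") 2L else 3L,
    elem = m[3],
    hcount = if (m[4] == "") NA_integer_ else as.integer(m[5]),
    charge = if (m[6] == "") 0L else as.integer(m[6])
  )
}

# --- encoding ---------------------------------------------------------------

selfies_encode_graph <- function(g) {
  a <- g$atoms
  if (any(a$arom) || any(!is.na(a$iso)) || !all(a$elem %in% names(.selfies_valence)))
    return(NULL)
  if (nrow(g$bonds) > 0L && any(!g$bonds$order %in% c(1, 2, 3))) return(NULL)

  n <- nrow(a)
  adj <- smiles_adjacency(g)
  visited <- logical(n); bond_used <- logical(nrow(g$bonds))
  order_of <- integer(n); children <- rep(list(integer(0)), n)
  ring_close <- rep(list(integer(0)), n)  # bonds closing at the later endpoint
  counter <- 0L
  walk <- function(u) {
    visited[u] <<- TRUE
    counter <<- counter + 1L
    order_of[u] <<- counter
    nbrs <- adj[[u]]$nbr; bnds <- adj[[u]]$bond
    for (j in order(nbrs)) {
      v <- nbrs[j]; k <- bnds[j]
      if (bond_used[k]) next
      bond_used[k] <<- TRUE
      if (visited[v]) ring_close[[u]] <<- c(ring_close[[u]], k)
      else { children[[u]] <<- c(children[[u]], k); walk(v) }
    }
  }
  walk(1L)

  atom_token <- function(u, order) {
    at <- a[u, ]
    hc <- if (is.na(at$hcount)) "" else paste0("H", at$hcount)
    chg <- if (at$charge == 0L) "" else sprintf("%+d", at$charge)
    paste0("[", selfies_bond_prefix(order), at$elem, hc, chg, "]")
  }

  emit <- function(u, order) {
    out <- atom_token(u, order)
    for (k in ring_close[[u]]) {
      other <- if (g$bonds$a1[k] == u) g$bonds$a2[k] else g$bonds$a1[k]
      q <- order_of[u] - order_of[other] - 1L
      nsym <- if (q < 16L) 1L else 2L
      ring_sym <- paste0("[", selfies_bond_prefix(g$bonds$order[k]), "Ring", nsym, "]")
      out <- c(out, ring_sym, selfies_spell_index(q, nsym))
    }
    kids <- children[[u]]
    nk <- length(kids)
    for (j in seq_along(kids)) {
      k <- kids[j]
      v <- if (g$bonds$a1[k] == u) g$bonds$a2[k] else g$bonds$a1[k]
      o <- g$bonds$order[k]
      sub <- emit(v, o)
      if (j < nk) {
        q <- length(sub) - 1L
        nsym <- if (q < 16L) 1L else 2L
        br <- paste0("[", selfies_bond_prefix(o), "Branch", nsym, "]")
        out <- c(out, br, selfies_spell_index(q, nsym), sub)
      } else {
        out <- c(out, sub)
      }
    }
    out
  }
  emit(1L, 1L)
}

#' Encode a SMILES molecule as a SELFIES token string
#'
#' Molecules outside the encodable dialect (aromatic lowercase form,
#' isotopes, unsupported elements) and unparseable or empty strings are
#' replaced by the single fallback token `"?"` rather than raising.
#'
#' @param s a SMILES string for one molecule.
#' @return a SELFIES token string, or `"?"`.
#' @export
to_selfies <- function(s) {
  if (is.na(s) || !nzchar(s)) return(SELFIES_FALLBACK)
  g <- tryCatch(smiles_parse(s), rxn_invalid_molecule = function(e) NULL)
  if (is.null(g)) return(SELFIES_FALLBACK)
  toks <- selfies_encode_graph(g)
  if (is.null(toks)) return(SELFIES_FALLBACK)
  paste(toks, collapse = "")
}

# --- decoding ---------------------------------------------------------------

#' Decode a SELFIES token string back to SMILES
#'
#' Total on well-formed token strings: bond orders are truncated to the
#' remaining valence of the atoms involved, and branch or ring symbols that
#' lack the required context are skipped, so every decodable string yields a
#' valid molecule. The fallback token `"?"` is not decodable.
#'
#' @param s a SELFIES token string.
#' @return a SMILES string.
#' @export
from_selfies <- function(s) {
  if (identical(s, SELFIES_FALLBACK))
    abort_rxn("the fallback token \"?\" is not decodable", class = "rxn_not_decodable")
  toks <- selfies_tokenize(s)
  toks <- toks[toks != "[nop]"]
  if (length(toks) == 0L)
    abort_rxn("empty SELFIES string is not decodable", class = "rxn_not_decodable")

  st <- new.env(parent = emptyenv())
  st$elem <- character(0); st$charge <- integer(0); st$hcount <- integer(0)
  st$b1 <- integer(0); st$b2 <- integer(0); st$bord <- numeric(0)
  st$rem <- numeric(0)

  add_atom <- function(at) {
    st$elem <- c(st$elem, at$elem)
    st$charge <- c(st$charge, at$charge)
    st$hcount <- c(st$hcount, at$hcount)
    v <- selfies_atom_valence(at$elem, at$charge) -
      (if (is.na(at$hcount)) 0L else at$hcount)
    st$rem <- c(st$rem, max(v, 0))
    length(st$elem)
  }
  add_bond <- function(a, b, o) {
    st$b1 <- c(st$b1, a); st$b2 <- c(st$b2, b); st$bord <- c(st$bord, o)
    st$rem[a] <- st$rem[a] - o; st$rem[b] <- st$rem[b] - o
  }

  # Derive `tokens` starting from attachment atom `attach` (NA at top level).
  # `init_order` is the bond order implied by an enclosing branch symbol,
  # used when the first atom token carries no bond prefix of its own.
  derive <- function(tokens, attach, init_order) {
    i <- 1L
    first <- TRUE
    while (i <= length(tokens)) {
      tok <- tokens[i]
      m <- regmatches(tok, regexec("^\\[(=|#)?(Branch|Ring)([123])\\]$", tok))[[1]]
      if (length(m) > 0L) {
        o <- if (m[2] == "") 1L else if (m[2] == "=") 2L else 3L
        nsym <- as.integer(m[4])
        idx_syms <- tokens[seq.int(i + 1L, length.out = min(nsym, length(tokens) - i))]
        q <- 0L
        for (sym in idx_syms) q <- q * 16L + selfies_index_value(sym)
        i <- i + 1L + length(idx_syms)
        if (m[3] == "Branch") {
          len <- q + 1L
          content <- tokens[seq.int(i, length.out = min(len, length(tokens) - i + 1L))]
          i <- i + length(content)
          if (!is.na(attach) && st$rem[attach] >= 1 && length(content) > 0L)
            derive(content, attach, o)
        } else {
          if (!is.na(attach)) {
            target <- max(1L, attach - (q + 1L))
            dup <- any((st$b1 == target & st$b2 == attach) | (st$b1 == attach & st$b2 == target))
            if (target != attach && !dup) {
              oo <- min(o, st$rem[attach], st$rem[target])
              if (oo >= 1) add_bond(target, attach, oo)
            }
          }
        }
        first <- FALSE
        next
      }
      at <- selfies_parse_atom_token(tok)
      i <- i + 1L
      if (is.null(at)) { first <- FALSE; next }   # unknown tokens act as no-ops
      o <- at$order
      if (first && !is.na(init_order) && o == 1L) o <- init_order
      first <- FALSE
      if (is.na(attach)) {
        attach <- add_atom(at)
      } else {
        if (st$rem[attach] < 1) break             # chain saturated: derivation stops
        cap <- selfies_atom_valence(at$elem, at$charge) -
          (if (is.na(at$hcount)) 0L else at$hcount)
        oo <- min(o, st$rem[attach], cap)
        if (oo < 1) break
        a <- add_atom(at)
        add_bond(attach, a, oo)
        attach <- a
      }
    }
    invisible(attach)
  }
  derive(toks, NA_integer_, NA_integer_)

  if (length(st$elem) == 0L)
    abort_rxn("SELFIES string derived no atoms", class = "rxn_not_decodable")
  g <- list(
    atoms = data.frame(elem = st$elem, arom = FALSE, charge = st$charge,
                       hcount = st$hcount, iso = NA_integer_, stringsAsFactors = FALSE),
    bonds = data.frame(a1 = st$b1, a2 = st$b2, order = st$bord)
  )
  smiles_write(g)
}

#' Convert a "."-joined reaction field between SMILES and SELFIES
#'
#' Applies [to_selfies()] / [from_selfies()] per molecule, preserving the
#' "." separator convention. Fallback "?" molecules survive a SELFIES
#' round trip as "?" but cannot be converted back to SMILES.
#'
#' @param s a "."-joined molecule string.
#' @return the converted "."-joined string.
#' @export
reaction_to_selfies <- function(s) {
  join_molecules(vapply(split_molecules(s), to_selfies, character(1), USE.NAMES = FALSE))
}

#' @rdname reaction_to_selfies
#' @export
reaction_from_selfies <- function(s) {
  join_molecules(vapply(split_molecules(s), from_selfies, character(1), USE.NAMES = FALSE))
}
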