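# Molecular graph data model and SMILES layer.
#
# Molecules are heavy-atom graphs: hydrogens are carried as per-atom counts
# (explicit counts from bracket atoms, or derived implicitly from the valence
# model), never as graph nodes. Bonds take one of four types: single, double,
# triple, aromatic. Internally a graph is a set of flat parallel vectors so
# the generation loop can append atoms/bonds cheaply; `atoms()` and `bonds()`
# expose tidy tibble views.

BOND_TYPES <- c("single", "double", "triple", "aromatic")
BOND_ORDER <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)

# Supported element vocabulary: common organic set.
# valences are the allowed total-valence sets for the neutral atom.
ELEMENTS <- list(
  B  = list(z = 5,  valences = 3,         aromatic_ok = TRUE,  organic = TRUE),
  C  = list(z = 6,  valences = 4,         aromatic_ok = TRUE,  organic = TRUE),
  N  = list(z = 7,  valences = 3,         aromatic_ok = TRUE,  organic = TRUE),
  O  = list(z = 8,  valences = 2,         aromatic_ok = TRUE,  organic = TRUE),
  F  = list(z = 9,  valences = 1,         aromatic_ok = FALSE, organic = TRUE),
  Si = list(z = 14, valences = 4,         aromatic_ok = FALSE, organic = FALSE),
  P  = list(z = 15, valences = c(3, 5),   aromatic_ok = TRUE,  organic = TRUE),
  S  = list(z = 16, valences = c(2, 4, 6),aromatic_ok = TRUE,  organic = TRUE),
  Cl = list(z = 17, valences = 1,         aromatic_ok = FALSE, organic = TRUE),
  Br = list(z = 35, valences = 1,         aromatic_ok = FALSE, organic = TRUE),
  I  = list(z = 53, valences = 1,         aromatic_ok = FALSE, organic = TRUE)
)

#' Supported chemical elements
#'
#' The element vocabulary accepted by the graph layer: the common organic set
#' C, N, O, S, F, Cl, Br, I, P, Si, B. Atoms outside this set are rejected at
#' parse time.
#'
#' @return A character vector of element symbols.
#' @export
supported_elements <- function() names(ELEMENTS)

element_z <- function(symbol) {
  vapply(symbol, function(s) ELEMENTS[[s]]$z, integer(1), USE.NAMES = FALSE)
}

# Allowed total valences for an element adjusted for formal charge.
# Lone-pair elements (N, O, P, S) gain valence with positive charge and lose
# it with negative charge; C/Si lose with either sign; B gains with negative.
allowed_valences <- function(element, charge) {
  base <- ELEMENTS[[element]]$valences
  v <- switch(element,
    N = , O = , P = , S = base + charge,
    C = , Si = base - abs(charge),
    B = base - charge,
    base + charge # halogens: X+ can be divalent in principle; keep simple
  )
  v[v >= 0]
}

max_valence <- function(element, charge) {
  v <- allowed_valences(element, charge)
  if (length(v) == 0) 0 else max(v)
}

#' Construct a molecular graph
#'
#' Low-level constructor. Most users will obtain graphs from
#' [parse_structure()] or from the generator; this builds one from explicit
#' atom and bond tables.
#'
#' @param atoms A data frame with columns `element` (symbol), `charge`
#'   (integer in -2..2), `h_explicit` (integer explicit-hydrogen count, or
#'   `NA` to derive hydrogens implicitly from the valence model), `aromatic`
#'   (logical).
#' @param bonds A data frame with columns `i`, `j` (1-based atom indices,
#'   `i < j`) and `type` (one of `"single"`, `"double"`, `"triple"`,
#'   `"aromatic"`).
#' @return A `mol_graph` object.
#' @export
mol_graph <- function(atoms = NULL, bonds = NULL) {
  g <- structure(list(
    element = character(0), charge = integer(0), h_explicit = integer(0),
    aromatic = logical(0),
    bi = integer(0), bj = integer(0), btype = character(0)
  ), class = "mol_graph")
  if (!is.null(atoms) && nrow(atoms) > 0) {
    stopifnot(all(atoms$element %in% supported_elements()),
              all(atoms$charge >= -2L & atoms$charge <= 2L))
    g$element <- as.character(atoms$element)
    g$charge <- as.integer(atoms$charge)
    g$h_explicit <- as.integer(atoms$h_explicit)
    g$aromatic <- as.logical(atoms$aromatic)
  }
  if (!is.null(bonds) && nrow(bonds) > 0) {
    i <- pmin(bonds$i, bonds$j); j <- pmax(bonds$i, bonds$j)
    if (any(i == j)) stop("self-loop bond")
    if (anyDuplicated(paste(i, j))) stop("duplicate bond")
    if (any(j > n_atoms(g))) stop("bond index out of range")
    if (!all(bonds$type %in% BOND_TYPES)) stop("unknown bond type")
    g$bi <- as.integer(i); g$bj <- as.integer(j); g$btype <- as.character(bonds$type)
  }
  g
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", n_atoms(x), " atoms, ", n_bonds(x), " bonds",
      if (n_atoms(x) > 0) paste0(" | ", tryCatch(write_structure(x),
                                                 error = function(e) "<fragment>")),
      "\n", sep = "")
  invisible(x)
}

#' Number of heavy atoms / bonds in a graph
#' @param g A `mol_graph`.
#' @return Integer count.
#' @export
n_atoms <- function(g) length(g$element)

#' @rdname n_atoms
#' @export
n_bonds <- function(g) length(g$bi)

#' Tidy views of a molecular graph
#'
#' @param g A `mol_graph`.
#' @return `atoms()`: a tibble with one row per heavy atom (element, formal
#'   charge, explicit-H count or `NA`, aromatic flag). `bonds()`: a tibble
#'   with one row per bond (`i`, `j`, `type`).
#' @export
atoms <- function(g) {
  tibble::tibble(element = g$element, charge = g$charge,
                 h_explicit = g$h_explicit, aromatic = g$aromatic)
}

#' @rdname atoms
#' @export
bonds <- function(g) {
  tibble::tibble(i = g$bi, j = g$bj, type = g$btype)
}

# fast internal mutators ------------------------------------------------

add_atom_ <- function(g, element, charge = 0L, h_explicit = NA_integer_,
                      aromatic = FALSE) {
  g$element <- c(g$element, element)
  g$charge <- c(g$charge, as.integer(charge))
  g$h_explicit <- c(g$h_explicit, as.integer(h_explicit))
  g$aromatic <- c(g$aromatic, aromatic)
  g
}

add_bond_ <- function(g, i, j, type) {
  ii <- min(i, j); jj <- max(i, j)
  g$bi <- c(g$bi, as.integer(ii)); g$bj <- c(g$bj, as.integer(jj))
  g$btype <- c(g$btype, type)
  if (type == "aromatic") g$aromatic[c(ii, jj)] <- TRUE
  g
}

has_bond <- function(g, i, j) {
  ii <- pmin(i, j); jj <- pmax(i, j)
  any(g$bi == ii & g$bj == jj)
}

# per-atom sum of bond orders (aromatic = 1.5) plus fixed explicit hydrogens
occupancy <- function(g) {
  occ <- ifelse(is.na(g$h_explicit), 0, g$h_explicit)
  if (n_bonds(g) > 0) {
    ord <- BOND_ORDER[g$btype]
    occ <- occ + tapply_sum(g$bi, ord, n_atoms(g)) +
      tapply_sum(g$bj, ord, n_atoms(g))
  }
  occ
}

tapply_sum <- function(idx, val, n) {
  out <- numeric(n)
  s <- rowsum(val, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

atom_degree <- function(g) {
  tabulate(c(g$bi, g$bj), nbins = n_atoms(g))
}

aromatic_degree <- function(g) {
  k <- g$btype == "aromatic"
  tabulate(c(g$bi[k], g$bj[k]), nbins = n_atoms(g))
}

# Capacity slack for aromatic atoms. Under the 1.5-per-aromatic-bond
# convention an atom's aromatic occupancy is 1.5 * adeg, but the Kekulé
# reality is adeg + 1 for atoms that take a double bond in the pi system and
# adeg for lone-pair donors (pyrrole N-H, furan O, ...). The capacity checks
# grant back the difference so that fused rings and donor heteroatoms close.
aromatic_slack <- function(adeg_after, needs_double) {
  pmax(0, 0.5 * adeg_after - as.numeric(needs_double))
}

# Permissive donor classification used by the capacity checks during
# construction: TRUE when the atom *could* complete as a pi lone-pair donor
# (its aromatic bonds would all kekulize to single bonds). Pyrrole-type
# nitrogens are donors even before their ring closes; structures that abuse
# the permissiveness are rejected by the kekulizability check at termination.
pi_can_donate <- function(g) {
  el <- g$element
  el %in% c("O", "S", "B") |
    (el %in% c("N", "P") & g$charge <= 0) |
    (el == "C" & g$charge != 0)
}

# atoms incident to a double or triple bond (aromatic and localized multiple
# bonds never mix on one atom: quinoid patterns are written kekulized)
has_multiple_bond <- function(g) {
  out <- rep(FALSE, n_atoms(g))
  k <- g$btype %in% c("double", "triple")
  out[unique(c(g$bi[k], g$bj[k]))] <- TRUE
  out
}

# vectorized max allowed valence
max_valence_vec <- function(element, charge) {
  mapply(function(e, c) max_valence(e, c), element, charge, USE.NAMES = FALSE)
}

# Effective per-atom valence cap inside a graph: atoms already in an
# aromatic system are held to their aromatic base valence (S stays
# thiophene-like divalent, O furan-like, ...), not to hypervalent states.
AROMATIC_BASE_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2)
max_valence_eff <- function(g) {
  v <- max_valence_vec(g$element, g$charge)
  ar <- which(g$aromatic)
  if (length(ar) > 0) {
    base <- AROMATIC_BASE_VALENCE[g$element[ar]]
    base <- ifelse(is.na(base), v[ar], base + pmax(g$charge[ar], 0))
    v[ar] <- pmin(v[ar], base)
  }
  v
}

# fast completed-molecule predicate without diagnostics
valid_complete_ <- function(g) {
  n <- n_atoms(g)
  if (n == 0) return(FALSE)
  adeg <- aromatic_degree(g)
  if (any(adeg == 1 | adeg > 3)) return(FALSE)
  if (any(adeg > 0 & has_multiple_bond(g))) return(FALSE)
  if (!is_connected(g)) return(FALSE)
  ord <- kekulize_orders(g)
  if (is.null(ord)) return(FALSE)
  bsum <- numeric(n)
  if (n_bonds(g) > 0) {
    bsum <- tapply_sum(g$bi, ord, n) + tapply_sum(g$bj, ord, n)
  }
  vme <- max_valence_eff(g)
  for (i in seq_len(n)) {
    allowed <- allowed_valences(g$element[i], g$charge[i])
    if (length(allowed) == 0) return(FALSE)
    if (!is.na(g$h_explicit[i])) {
      if (!(bsum[i] + g$h_explicit[i]) %in% allowed) return(FALSE)
      if (bsum[i] + g$h_explicit[i] > vme[i]) return(FALSE)
    } else if (bsum[i] > vme[i]) return(FALSE)
  }
  TRUE
}

#' Is the heavy-atom graph connected?
#'
#' @param g A `mol_graph`.
#' @return Logical. The empty graph and single atoms count as connected.
#' @export
is_connected <- function(g) {
  n <- n_atoms(g)
  if (n <= 1) return(TRUE)
  seen <- logical(n); seen[1] <- TRUE; frontier <- 1L
  nb <- neighbor_list(g)
  while (length(frontier) > 0) {
    nxt <- unique(unlist(nb[frontier]))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

neighbor_list <- function(g) {
  n <- n_atoms(g)
  nb <- vector("list", n)
  if (n_bonds(g) > 0) {
    for (k in seq_len(n_bonds(g))) {
      nb[[g$bi[k]]] <- c(nb[[g$bi[k]]], g$bj[k])
      nb[[g$bj[k]]] <- c(nb[[g$bj[k]]], g$bi[k])
    }
  }
  nb
}

# SMILES parsing ---------------------------------------------------------

#' Parse a SMILES string into a molecular graph
#'
#' Accepts the organic-subset atoms `B C N O P S F Cl Br I` (and their
#' aromatic lowercase forms), bracket atoms with charge and explicit-hydrogen
#' counts, branches, and ring-closure digits (including `%nn`). The parsed
#' graph is sanitized: aromatic systems must kekulize and every atom must
#' satisfy the valence model, otherwise an error describes the offending
#' atom or token. Stereo markers (`/ \ @`) are accepted and discarded;
#' isotopes are ignored.
#'
#' @param smiles A single SMILES string.
#' @return A `mol_graph`.
#' @examples
#' g <- parse_structure("O=[N+]([O-])c1ccccc1") # nitrobenzene, 9 heavy atoms
#' n_atoms(g)
#' @export
parse_structure <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles) ||
      nchar(trimws(smiles)) == 0) {
    stop("parse error: empty or non-character SMILES input")
  }
  s <- trimws(smiles)
  g <- mol_graph()
  prev <- NA_integer_          # atom to bond the next atom to
  pending_bond <- NULL         # explicit bond symbol awaiting next atom
  stack <- integer(0)          # branch stack
  rings <- list()              # ring-closure slots: id -> list(atom, bond)
  pos <- 1L
  nc <- nchar(s)

  emit_atom <- function(element, charge, h_explicit, aromatic) {
    if (!(element %in% supported_elements())) {
      stop(sprintf("parse error: unsupported element '%s' at position %d",
                   element, pos))
    }
    if (aromatic && !ELEMENTS[[element]]$aromatic_ok) {
      stop(sprintf("parse error: element '%s' cannot be aromatic (position %d)",
                   element, pos))
    }
    if (charge < -2 || charge > 2) {
      stop(sprintf("parse error: formal charge %+d out of range at position %d",
                   charge, pos))
    }
    g <<- add_atom_(g, element, charge, h_explicit, aromatic)
    idx <- n_atoms(g)
    if (!is.na(prev)) {
      type <- resolve_bond(pending_bond, g$aromatic[prev], aromatic)
      g <<- add_bond_(g, prev, idx, type)
    }
    pending_bond <<- NULL
    prev <<- idx
  }

  close_ring <- function(id) {
    if (!is.null(rings[[id]])) {
      open <- rings[[id]]
      rings[[id]] <<- NULL
      if (is.na(prev)) stop("parse error: ring closure before any atom")
      if (open$atom == prev) stop("parse error: ring closure to itself")
      sym <- if (!is.null(pending_bond)) pending_bond else open$bond
      type <- resolve_bond(sym, g$aromatic[open$atom], g$aromatic[prev])
      if (has_bond(g, open$atom, prev)) {
        stop("parse error: duplicate ring-closure bond")
      }
      g <<- add_bond_(g, open$atom, prev, type)
      pending_bond <<- NULL
    } else {
      if (is.na(prev)) stop("parse error: ring opening before any atom")
      rings[[id]] <<- list(atom = prev, bond = pending_bond)
      pending_bond <<- NULL
    }
  }

  while (pos <= nc) {
    ch <- substr(s, pos, pos)
    two <- substr(s, pos, pos + 1L)
    if (ch == "[") {
      end <- regexpr("]", substr(s, pos, nc), fixed = TRUE)
      if (end < 0) stop(sprintf("parse error: unclosed '[' at position %d", pos))
      body <- substr(s, pos + 1L, pos + end - 2L)
      at <- parse_bracket_atom(body, pos)
      emit_atom(at$element, at$charge, at$h, at$aromatic)
      pos <- pos + end
    } else if (two %in% c("Cl", "Br")) {
      emit_atom(two, 0L, NA_integer_, FALSE); pos <- pos + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      emit_atom(ch, 0L, NA_integer_, FALSE); pos <- pos + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      emit_atom(toupper(ch), 0L, NA_integer_, TRUE); pos <- pos + 1L
    } else if (ch %in% c("-", "=", "#", ":")) {
      pending_bond <- ch; pos <- pos + 1L
    } else if (ch %in% c("/", "\\")) {
      pending_bond <- "-"; pos <- pos + 1L # stereo bond: treat as single
    } else if (ch == "(") {
      if (is.na(prev)) stop("parse error: branch before any atom")
      stack <- c(stack, prev); pos <- pos + 1L
    } else if (ch == ")") {
      if (length(stack) == 0) stop("parse error: unmatched ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      pos <- pos + 1L
    } else if (grepl("^[0-9]$", ch)) {
      close_ring(ch); pos <- pos + 1L
    } else if (ch == "%") {
      id <- substr(s, pos + 1L, pos + 2L)
      if (!grepl("^[0-9]{2}$", id)) {
        stop(sprintf("parse error: malformed ring label at position %d", pos))
      }
      close_ring(id); pos <- pos + 3L
    } else if (ch == ".") {
      stop("parse error: multi-fragment SMILES ('.') not supported")
    } else {
      stop(sprintf("parse error: unexpected character '%s' at position %d",
                   ch, pos))
    }
  }
  if (length(stack) > 0) stop("parse error: unclosed branch '('")
  if (length(rings) > 0 && any(!vapply(rings, is.null, logical(1)))) {
    stop("parse error: unclosed ring bond")
  }
  if (n_atoms(g) == 0) stop("parse error: no atoms in input")
  ok <- validate_valence(g)
  if (!ok) {
    d <- attr(ok, "diagnostics")
    stop(sprintf("valence error: %s (atom %d, %s)",
                 d$reason[1], d$atom[1], d$element[1]))
  }
  g
}

parse_bracket_atom <- function(body, pos) {
  m <- regmatches(body,
    regexec("^([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H[0-9]*)?([+-][0-9]*|[+]{1,2}|[-]{1,2})?$",
            body))[[1]]
  if (length(m) == 0) {
    stop(sprintf("parse error: malformed bracket atom '[%s]' at position %d",
                 body, pos))
  }
  sym <- m[3]
  aromatic <- sym == tolower(sym) && nchar(sym) == 1
  element <- if (aromatic) toupper(sym) else sym
  h <- 0L
  if (nzchar(m[5])) {
    h <- if (m[5] == "H") 1L else as.integer(sub("H", "", m[5]))
  }
  charge <- 0L
  cs <- m[6]
  if (nzchar(cs)) {
    if (grepl("^[+-][0-9]+$", cs)) {
      charge <- as.integer(cs)
    } else {
      charge <- (nchar(cs)) * if (substr(cs, 1, 1) == "+") 1L else -1L
    }
  }
  list(element = element, charge = charge, h = h, aromatic = aromatic)
}

resolve_bond <- function(symbol, arom_a, arom_b) {
  if (is.null(symbol)) {
    if (isTRUE(arom_a) && isTRUE(arom_b)) "aromatic" else "single"
  } else {
    switch(symbol, "-" = "single", "=" = "double", "#" = "triple",
           ":" = "aromatic", stop("parse error: bad bond symbol"))
  }
}

# SMILES writing ---------------------------------------------------------

#' Write a molecular graph as a SMILES string
#'
#' Emits a (non-canonical) SMILES by depth-first traversal from atom 1.
#' Aromatic atoms are written lowercase; bracket notation is used whenever
#' the atom carries a formal charge or a pinned explicit-hydrogen count.
#' For a canonical, order-independent string use [canonical_form()].
#'
#' @param g A connected `mol_graph` (fragments being built are fine; the
#'   writer does not validate valence).
#' @return A SMILES string.
#' @export
write_structure <- function(g) {
  n <- n_atoms(g)
  if (n == 0) stop("cannot write an empty graph")
  if (!is_connected(g)) stop("cannot write a disconnected graph")
  nb <- neighbor_list(g)
  bond_type_of <- function(i, j) {
    ii <- min(i, j); jj <- max(i, j)
    g$btype[g$bi == ii & g$bj == jj][1]
  }
  visited <- logical(n)
  ring_id <- 0L
  ring_labels <- list() # key "i-j" -> digit label
  # pre-pass: find ring-closure edges via DFS tree
  tree_parent <- rep(NA_integer_, n)
  closure_edges <- character(0)
  st <- 1L; visited[1] <- TRUE; order <- integer(0)
  stack2 <- list(1L)
  while (length(stack2) > 0) {
    u <- stack2[[length(stack2)]]; stack2[[length(stack2)]] <- NULL
    order <- c(order, u)
    for (v in nb[[u]]) {
      if (!visited[v]) {
        visited[v] <- TRUE; tree_parent[v] <- u
        stack2[[length(stack2) + 1L]] <- v
      } else if (!identical(tree_parent[u], v)) {
        key <- paste(min(u, v), max(u, v), sep = "-")
        if (!key %in% closure_edges) closure_edges <- c(closure_edges, key)
      }
    }
  }
  for (key in closure_edges) {
    ring_id <- ring_id + 1L
    ring_labels[[key]] <- if (ring_id < 10) as.character(ring_id)
                          else paste0("%", ring_id)
  }
  bond_sym <- function(type, arom_a, arom_b) {
    switch(type,
      single = if (isTRUE(arom_a) && isTRUE(arom_b)) "-" else "",
      double = "=", triple = "#",
      aromatic = "")
  }
  atom_token <- function(i) {
    el <- g$element[i]
    sym <- if (g$aromatic[i]) tolower(el) else el
    needs_bracket <- g$charge[i] != 0 || !is.na(g$h_explicit[i]) ||
      !ELEMENTS[[el]]$organic || (g$aromatic[i] && nchar(el) > 1)
    if (!needs_bracket) return(sym)
    h <- g$h_explicit[i]
    htxt <- if (is.na(h)) {
      ih <- implicit_h_single(g, i)
      if (ih == 0) "" else if (ih == 1) "H" else paste0("H", ih)
    } else if (h == 0) "" else if (h == 1) "H" else paste0("H", h)
    ctxt <- if (g$charge[i] == 0) "" else
      sprintf("%s%s", if (g$charge[i] > 0) "+" else "-",
              if (abs(g$charge[i]) == 1) "" else abs(g$charge[i]))
    paste0("[", sym, htxt, ctxt, "]")
  }
  visited2 <- logical(n)
  emit <- function(u, from) {
    visited2[u] <<- TRUE
    out <- atom_token(u)
    # ring closures at this atom
    for (v in nb[[u]]) {
      key <- paste(min(u, v), max(u, v), sep = "-")
      if (!is.null(ring_labels[[key]])) {
        bs <- bond_sym(bond_type_of(u, v), g$aromatic[u], g$aromatic[v])
        out <- paste0(out, bs, ring_labels[[key]])
      }
    }
    children <- nb[[u]][!visited2[nb[[u]]] &
                        !vapply(nb[[u]], function(v)
                          !is.null(ring_labels[[paste(min(u, v), max(u, v),
                                                      sep = "-")]]),
                          logical(1))]
    if (length(children) > 0) {
      parts <- character(0)
      for (k in seq_along(children)) {
        v <- children[k]
        if (visited2[v]) next
        bs <- bond_sym(bond_type_of(u, v), g$aromatic[u], g$aromatic[v])
        sub <- paste0(bs, emit(v, u))
        parts <- c(parts, sub)
      }
      if (length(parts) > 1) {
        out <- paste0(out,
          paste0("(", parts[-length(parts)], ")", collapse = ""),
          parts[length(parts)])
      } else if (length(parts) == 1) {
        out <- paste0(out, parts[1])
      }
    }
    out
  }
  emit(1L, NA_integer_)
}

implicit_h_single <- function(g, i) {
  h <- implicit_h_counts(g, strict = FALSE)
  h[i]
}

# Kekulization & valence -------------------------------------------------

# Resolve aromatic bonds to alternating single/double. Returns the vector of
# kekulized bond orders, or NULL if the aromatic system cannot kekulize.
kekulize_orders <- function(g) {
  ord <- unname(BOND_ORDER[g$btype])
  ar <- which(g$btype == "aromatic")
  if (length(ar) == 0) return(ord)
  ord[ar] <- 1 # sigma frame
  needs <- pi_needs_double(g)
  # matching restricted to aromatic bonds whose two endpoints both need a double
  arom_atoms <- sort(unique(c(g$bi[ar], g$bj[ar])))
  need_atoms <- arom_atoms[needs[arom_atoms]]
  if (length(need_atoms) == 0) return(ord)
  cand <- ar[needs[g$bi[ar]] & needs[g$bj[ar]]]
  adj <- lapply(seq_len(n_atoms(g)), function(i) integer(0))
  for (k in cand) {
    adj[[g$bi[k]]] <- c(adj[[g$bi[k]]], k)
    adj[[g$bj[k]]] <- c(adj[[g$bj[k]]], k)
  }
  matched <- logical(n_atoms(g))
  chosen <- logical(length(g$btype))
  try_match <- function(remaining) {
    if (length(remaining) == 0) return(TRUE)
    u <- remaining[1]
    if (matched[u]) return(try_match(remaining[-1]))
    for (k in adj[[u]]) {
      v <- if (g$bi[k] == u) g$bj[k] else g$bi[k]
      if (matched[v]) next
      matched[u] <<- TRUE; matched[v] <<- TRUE; chosen[k] <<- TRUE
      if (try_match(remaining[-1])) return(TRUE)
      matched[u] <<- FALSE; matched[v] <<- FALSE; chosen[k] <<- FALSE
    }
    FALSE
  }
  if (!try_match(need_atoms)) return(NULL)
  ord[chosen] <- 2
  ord
}

# Which atoms would have to receive one double bond in a Kekulé structure
# (vs. contributing a lone pair / empty orbital) if they sit in an aromatic
# system? Computed for every atom so capacity checks can consult it before
# an atom has acquired aromatic bonds.
pi_needs_double <- function(g) {
  n <- n_atoms(g)
  needs <- rep(FALSE, n)
  deg <- atom_degree(g)
  has_exo_multiple <- rep(FALSE, n)
  exo <- g$btype %in% c("double", "triple")
  has_exo_multiple[unique(c(g$bi[exo], g$bj[exo]))] <- TRUE
  for (i in seq_len(n)) {
    el <- g$element[i]; ch <- g$charge[i]
    h <- g$h_explicit[i]
    needs[i] <- switch(el,
      C = !has_exo_multiple[i] && ch == 0,
      N = if (ch == 1) TRUE
          else if (ch == -1) FALSE
          else (deg[i] + ifelse(is.na(h), 0, h)) <= 2, # pyridine-type
      P = (deg[i] + ifelse(is.na(h), 0, h)) <= 2,
      O = FALSE, S = FALSE, B = FALSE,
      FALSE)
  }
  needs
}

#' Implicit hydrogen counts
#'
#' Derives the number of implicit hydrogens per atom: for atoms with a pinned
#' explicit-H count this is 0; otherwise it is the gap between the atom's
#' (kekulized) bond-order sum and the smallest allowed valence that covers it.
#'
#' @param g A `mol_graph`.
#' @param strict Error if the aromatic system cannot kekulize (default);
#'   otherwise fall back to aromatic bond order 1.5 rounded up.
#' @return Integer vector, one entry per atom.
#' @export
implicit_h_counts <- function(g, strict = TRUE) {
  ord <- kekulize_orders(g)
  if (is.null(ord)) {
    if (strict) stop("aromatic system cannot be kekulized")
    ord <- unname(BOND_ORDER[g$btype])
  }
  bsum <- numeric(n_atoms(g))
  if (n_bonds(g) > 0) {
    bsum <- tapply_sum(g$bi, ord, n_atoms(g)) + tapply_sum(g$bj, ord, n_atoms(g))
  }
  bsum <- ceiling(bsum)
  out <- integer(n_atoms(g))
  for (i in seq_len(n_atoms(g))) {
    if (!is.na(g$h_explicit[i])) { out[i] <- 0L; next }
    v <- allowed_valences(g$element[i], g$charge[i])
    v <- v[v >= bsum[i]]
    out[i] <- if (length(v) == 0) 0L else as.integer(min(v) - bsum[i])
  }
  out
}

#' Validate atom valences of a completed molecule
#'
#' Checks that every atom's total bond order plus hydrogens lies in the
#' allowed-valence set of its element adjusted for formal charge. Aromatic
#' systems are accepted via kekulizability: aromatic bonds must resolve to an
#' alternating single/double assignment, and every atom carrying aromatic
#' bonds must have aromatic degree 2 or 3 (i.e. aromatic bonds close rings).
#'
#' @param g A `mol_graph`.
#' @return `TRUE` or `FALSE`; on failure the `"diagnostics"` attribute holds
#'   a tibble with columns `atom`, `element`, `reason`.
#' @examples
#' validate_valence(parse_structure("c1ccccc1"))          # TRUE
#' @export
validate_valence <- function(g) {
  bad <- tibble::tibble(atom = integer(0), element = character(0),
                        reason = character(0))
  fail <- function(i, reason) {
    bad <<- dplyr::bind_rows(bad, tibble::tibble(
      atom = i, element = g$element[i], reason = reason))
  }
  adeg <- aromatic_degree(g)
  for (i in which(adeg == 1 | adeg > 3)) {
    fail(i, sprintf("aromatic degree %d (aromatic bonds must close rings)",
                    adeg[i]))
  }
  for (i in which(adeg > 0 & has_multiple_bond(g))) {
    fail(i, "aromatic and localized multiple bonds mixed on one atom")
  }
  ord <- NULL
  if (nrow(bad) == 0) {
    ord <- kekulize_orders(g)
    if (is.null(ord)) {
      i <- which(adeg > 0)[1]
      fail(i, "aromatic system cannot be kekulized")
    }
  }
  if (nrow(bad) == 0) {
    bsum <- numeric(n_atoms(g))
    if (n_bonds(g) > 0) {
      bsum <- tapply_sum(g$bi, ord, n_atoms(g)) +
        tapply_sum(g$bj, ord, n_atoms(g))
    }
    vme <- max_valence_eff(g)
    for (i in seq_len(n_atoms(g))) {
      allowed <- allowed_valences(g$element[i], g$charge[i])
      if (length(allowed) == 0) { fail(i, "no allowed valence for charge"); next }
      if (!is.na(g$h_explicit[i])) {
        tot <- bsum[i] + g$h_explicit[i]
        if (!tot %in% allowed || tot > vme[i]) {
          fail(i, sprintf("total valence %g not allowed", tot))
        }
      } else {
        if (bsum[i] > vme[i]) {
          fail(i, sprintf("bond-order sum %g exceeds allowed valence %g",
                          bsum[i], vme[i]))
        }
      }
    }
  }
  out <- nrow(bad) == 0
  attr(out, "diagnostics") <- bad
  out
}

#' Completed-molecule check
#'
#' A finished molecule must be non-empty, connected, and pass
#' [validate_valence()].
#'
#' @param g A `mol_graph`.
#' @return Logical.
#' @export
molecule_ok <- function(g) {
  valid_complete_(g)
}

# Canonicalization -------------------------------------------------------

#' Canonical form of a molecule
#'
#' Returns a unique, atom-order-independent SMILES string, used throughout
#' as the database key (uniqueness/novelty counting, reference lookup).
#' Canonical ordering is delegated to OpenBabel.
#'
#' @param x A `mol_graph`, or a character vector of SMILES strings.
#' @return A character vector of canonical SMILES.
#' @examples
#' canonical_form(parse_structure("C1=CC=CC=C1")) ==
#'   canonical_form(parse_structure("c1ccccc1"))
#' @export
canonical_form <- function(x) {
  if (inherits(x, "mol_graph")) {
    if (!molecule_ok(x)) stop("cannot canonicalize an invalid or incomplete molecule")
    x <- write_structure(x)
  }
  stopifnot(is.character(x), length(x) >= 1)
  out <- ChemmineOB::convertFormat("SMI", "CAN", paste(x, collapse = "\n"))
  out <- strsplit(out, "\n", fixed = TRUE)[[1]]
  out <- sub("\t.*$", "", out)
  out <- trimws(out)
  out <- out[nzchar(out)]
  if (length(out) != length(x)) {
    stop("canonicalization failed for at least one structure")
  }
  out
}

# Batch canonicalization with a per-molecule fallback: structures the
# canonicalization backend cannot process keep their input spelling as key.
canonical_safe <- function(x) {
  out <- tryCatch(suppressWarnings(canonical_form(x)),
                  error = function(e) NULL)
  if (!is.null(out)) return(out)
  vapply(x, function(s)
    tryCatch(suppressWarnings(canonical_form(s)), error = function(e) s),
    character(1), USE.NAMES = FALSE)
}

# Conjugation ------------------------------------------------------------

#' Conjugated components of a molecule
#'
#' A bond belongs to the conjugated system if it is double, triple or
#' aromatic, or if it is a single bond whose two endpoints both carry a
#' multiple/aromatic bond (sp- or sp2-hybridized atoms bridged by a single
#' bond, as in styrene's ring--vinyl link). Components are the connected
#' groups of such bonds.
#'
#' @param g A valid `mol_graph`.
#' @return A list of integer vectors, each the bond indices (rows of
#'   `bonds(g)`) of one conjugated component. Empty list if the molecule has
#'   no pi system.
#' @examples
#' length(conjugated_components(parse_structure("c1ccccc1"))) # 1
#' @export
conjugated_components <- function(g) {
  if (n_bonds(g) == 0) return(list())
  multi <- g$btype %in% c("double", "triple", "aromatic")
  pi_atom <- rep(FALSE, n_atoms(g))
  pi_atom[unique(c(g$bi[multi], g$bj[multi]))] <- TRUE
  conj <- multi | (g$btype == "single" & pi_atom[g$bi] & pi_atom[g$bj])
  idx <- which(conj)
  if (length(idx) == 0) return(list())
  # connected components of the conjugated bond set (bonds sharing an atom)
  eg <- igraph::graph_from_edgelist(
    cbind(g$bi[idx], g$bj[idx]), directed = FALSE)
  comp <- igraph::components(eg)$membership
  split(idx, comp[g$bi[idx]])
}
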