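# Shared fixtures and independent oracles for the test suite.
# Everything is built in code at test time; expensive objects (synthetic
# database, trained model) are memoised for the session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# a small curated set of valid SMILES spanning the supported chemistry
valid_smiles_fixture <- function() {
  c("C", "CC", "CCO", "C=C", "C#N", "c1ccccc1", "C1=CC=CC=C1",
    "n1ccccc1", "c1cc[nH]c1", "c1ccoc1", "c1ccsc1", "Cn1cccc1",
    "c1ccc2ccccc2c1", "C=Cc1ccccc1", "CC(=O)Oc1ccccc1C(O)=O",
    "O=[N+]([O-])c1ccccc1", "Nc1ccc(cc1)[N+](=O)[O-]",
    "FC(F)(F)c1ccccc1", "C#Cc1ccccc1", "N#Cc1ccc(cc1)N(C)C",
    "CC(C)(C)C", "OCC(O)CO", "CS(=O)(=O)C", "c1ccccc1-c1ccccc1",
    "C=CC=CC=C", "CN(C)c1ccc(cc1)C=O")
}

invalid_smiles_fixture <- function() {
  c("C(", "C1CC", "c1ccccc", "C(C)(C)(C)(C)C", "[Xx]", "", "C..C",
    "C%1", "C)C")
}

# structure-only condition helper around the database median
median_condition <- function(db, solvent = "toluene", ...) {
  out <- lapply(fluogen:::PROPERTY_NAMES, function(p)
    stats::median(db[[p]], na.rm = TRUE))
  names(out) <- fluogen:::PROPERTY_NAMES
  out$solvent <- solvent
  mods <- list(...)
  out[names(mods)] <- mods
  out
}

test_db <- function() {
  memo("db", synth_database(120, seed = 404, size_range = c(6L, 12L)))
}

test_model <- function() {
  memo("model", train_generator(
    test_db(), model_config(epochs = 2, seed = 7), quiet = TRUE))
}

# ---- independent oracle: degree of conjugation by plain BFS ------------

# conjugated bond rule restated independently: double/triple/aromatic bonds,
# plus single bonds whose both ends touch such a bond
bfs_doc_oracle <- function(g) {
  b <- bonds(g)
  if (nrow(b) == 0) return(0L)
  multi <- b$type %in% c("double", "triple", "aromatic")
  pi_atoms <- unique(c(b$i[multi], b$j[multi]))
  conj <- multi | (b$type == "single" & b$i %in% pi_atoms &
                     b$j %in% pi_atoms)
  if (!any(conj)) return(0L)
  eb <- b[conj, ]
  verts <- sort(unique(c(eb$i, eb$j)))
  adj <- lapply(verts, function(v)
    c(eb$j[eb$i == v], eb$i[eb$j == v]))
  names(adj) <- as.character(verts)
  best <- 0L
  for (src in verts) {
    dist <- stats::setNames(rep(NA_integer_, length(verts)),
                            as.character(verts))
    dist[as.character(src)] <- 0L
    queue <- src
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[as.character(v)]]) {
        if (is.na(dist[as.character(w)])) {
          dist[as.character(w)] <- dist[as.character(v)] + 1L
          queue <- c(queue, w)
        }
      }
    }
    best <- max(best, max(dist, na.rm = TRUE))
  }
  as.integer(best)
}

# ---- independent oracle: brute-force legal-action check ----------------

# independent element table (restated, not imported)
.bf_valences <- list(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4,
                     P = c(3, 5), S = c(2, 4, 6), Cl = 1, Br = 1, I = 1)
.bf_arom_ok <- c("B", "C", "N", "O", "P", "S")
.bf_arom_base <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2)

bf_allowed <- function(el, ch) {
  base <- .bf_valences[[el]]
  v <- if (el %in% c("N", "O", "P", "S")) base + ch
       else if (el %in% c("C", "Si")) base - abs(ch)
       else if (el == "B") base - ch
       else base + ch
  v[v >= 0]
}

bf_order <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)

# Can this atom act as a pi lone-pair donor (same documented rule)?
bf_can_donate <- function(el, ch, has_exo_multi) {
  if (el %in% c("O", "S", "B")) return(TRUE)
  if (el %in% c("N", "P")) return(ch <= 0)
  if (el == "C") return(ch != 0)
  FALSE
}

# Independent intermediate-state validity predicate for a graph given as
# atoms/bonds tibbles (the documented construction rules, restated).
bf_state_ok <- function(at, bd) {
  if (nrow(bd) > 0) {
    if (any(bd$i == bd$j)) return(FALSE)
    if (anyDuplicated(paste(pmin(bd$i, bd$j), pmax(bd$i, bd$j)))) {
      return(FALSE)
    }
  }
  n <- nrow(at)
  for (k in seq_len(n)) {
    bk <- bd[bd$i == k | bd$j == k, ]
    occ <- sum(bf_order[bk$type]) +
      ifelse(is.na(at$h_explicit[k]), 0, at$h_explicit[k])
    adeg <- sum(bk$type == "aromatic")
    if (adeg > 3) return(FALSE)
    if (adeg > 0 && !(at$element[k] %in% .bf_arom_ok)) return(FALSE)
    exo <- any(bk$type %in% c("double", "triple"))
    if (adeg > 0 && exo) return(FALSE) # no quinoid mixing on one atom
    needs <- !bf_can_donate(at$element[k], at$charge[k], exo)
    slack <- max(0, 0.5 * adeg - as.numeric(needs))
    cap <- max(bf_allowed(at$element[k], at$charge[k]))
    if (adeg > 0) {
      cap <- min(cap, .bf_arom_base[[at$element[k]]] +
                   max(at$charge[k], 0))
    }
    if (occ > cap + slack + 1e-9) return(FALSE)
  }
  TRUE
}

# Independent completed-molecule predicate: connectivity, aromatic bonds in
# rings, an exhaustive Kekule search, and exact valence totals.
bf_complete_ok <- function(at, bd) {
  n <- nrow(at)
  if (n == 0) return(FALSE)
  if (!bf_state_ok(at, bd)) return(FALSE)
  # connectivity
  if (n > 1) {
    seen <- logical(n); seen[1] <- TRUE; repeat {
      new <- unique(c(bd$j[seen[bd$i]], bd$i[seen[bd$j]]))
      new <- new[!seen[new]]
      if (length(new) == 0) break
      seen[new] <- TRUE
    }
    if (!all(seen)) return(FALSE)
  }
  adeg <- vapply(seq_len(n), function(k)
    sum(bd$type == "aromatic" & (bd$i == k | bd$j == k)), numeric(1))
  if (any(adeg == 1)) return(FALSE)
  # exhaustive Kekule assignment over aromatic bonds
  ar <- which(bd$type == "aromatic")
  assign_ok <- function(orders) {
    for (k in seq_len(n)) {
      bk <- which(bd$i == k | bd$j == k)
      tot <- sum(orders[bk]) +
        ifelse(is.na(at$h_explicit[k]), 0, at$h_explicit[k])
      allowed <- bf_allowed(at$element[k], at$charge[k])
      cap <- max(allowed)
      if (adeg[k] > 0) {
        cap <- min(cap, .bf_arom_base[[at$element[k]]] +
                     max(at$charge[k], 0))
      }
      ok <- if (is.na(at$h_explicit[k])) {
        tot <= cap
      } else {
        (tot %in% allowed) && tot <= cap
      }
      if (!ok) return(FALSE)
    }
    TRUE
  }
  base_orders <- unname(bf_order[bd$type])
  if (length(ar) == 0) return(assign_ok(base_orders))
  # each aromatic atom gets exactly one double among its aromatic bonds if
  # it needs one, zero otherwise; search all 2^|ar| (small graphs only)
  for (mask in 0:(2^length(ar) - 1)) {
    orders <- base_orders
    dbl <- ar[bitwAnd(mask, 2^(seq_along(ar) - 1)) > 0]
    orders[ar] <- 1
    orders[dbl] <- 2
    good <- TRUE
    for (k in which(adeg > 0)) {
      bk <- which((bd$i == k | bd$j == k) & bd$type == "aromatic")
      ndbl <- sum(bk %in% dbl)
      exo <- any(bd$type[bd$i == k | bd$j == k] %in% c("double", "triple"))
      needs <- !bf_can_donate(at$element[k], at$charge[k], exo)
      if (ndbl != as.numeric(needs)) { good <- FALSE; break }
    }
    if (good && assign_ok(orders)) return(TRUE)
  }
  FALSE
}

# Brute-force reference for legal_actions: build every candidate action,
# apply it naively, and keep those whose result passes the independent
# validity predicate. Returns the same candidate ordering as legal_actions.
bf_legal_mask <- function(g, vocab) {
  at <- atoms(g); bd <- bonds(g)
  n <- nrow(at)
  cand <- legal_actions(g, vocab) # candidate list only; mask recomputed
  mask <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    k <- cand$kind[r]
    if (k == "add") {
      if (n == 0) {
        mask[r] <- is.na(cand$attach[r])
        next
      }
      if (is.na(cand$attach[r])) { mask[r] <- FALSE; next }
      at2 <- rbind(at, tibble::tibble(
        element = cand$element[r], charge = cand$charge[r],
        h_explicit = cand$h_explicit[r],
        aromatic = identical(cand$bond[r], "aromatic")))
      bd2 <- rbind(bd, tibble::tibble(
        i = cand$attach[r], j = n + 1L, type = cand$bond[r]))
      at2$aromatic[cand$attach[r]] <- at2$aromatic[cand$attach[r]] ||
        cand$bond[r] == "aromatic"
      mask[r] <- bf_state_ok(at2, bd2) &&
        cand$bond[r] %in% names(bf_order)
      # new-atom valence: its single bond + pinned hydrogens must fit
      if (mask[r]) {
        h <- ifelse(is.na(cand$h_explicit[r]), 0, cand$h_explicit[r])
        mask[r] <- bf_order[[cand$bond[r]]] + h <=
          max(bf_allowed(cand$element[r], cand$charge[r])) + 1e-9
      }
    } else if (k == "connect") {
      bd2 <- rbind(bd, tibble::tibble(i = cand$i[r], j = cand$j[r],
                                      type = cand$bond[r]))
      at2 <- at
      if (cand$bond[r] == "aromatic") {
        at2$aromatic[c(cand$i[r], cand$j[r])] <- TRUE
      }
      dup <- any(pmin(bd$i, bd$j) == min(cand$i[r], cand$j[r]) &
                   pmax(bd$i, bd$j) == max(cand$i[r], cand$j[r]))
      mask[r] <- !dup && bf_state_ok(at2, bd2)
    } else {
      mask[r] <- bf_complete_ok(at, bd)
    }
  }
  # escape termination: if nothing else is legal, terminate becomes legal
  if (n > 0 && !any(mask)) mask[cand$kind == "terminate"] <- TRUE
  list(cand = cand, mask = mask)
}

# isomorphism-class key for small graphs: bond types are encoded as colored
# subdivision vertices so BLISS canonical labeling sees them
iso_key <- function(g) {
  n <- n_atoms(g)
  if (n == 0) return("empty")
  akey <- paste(g$element, g$charge, g$h_explicit)
  acol <- match(akey, sort(unique(akey))) # order-independent color table
  m <- n_bonds(g)
  bcol <- match(g$btype, BOND_TYPES) + max(acol)
  el <- NULL
  if (m > 0) {
    bv <- n + seq_len(m)
    el <- rbind(cbind(g$bi, bv), cbind(g$bj, bv))
  }
  ig <- igraph::make_empty_graph(n + m, directed = FALSE)
  if (!is.null(el)) ig <- igraph::add_edges(ig, t(el))
  colors <- c(acol, if (m > 0) bcol)
  cp <- igraph::canonical_permutation(ig, colors = colors)
  pg <- igraph::permute(ig, cp$labeling)
  el2 <- igraph::as_edgelist(pg)
  ek <- sort(paste(pmin(el2[, 1], el2[, 2]), pmax(el2[, 1], el2[, 2]),
                   sep = "-"))
  paste(paste(sort(akey), collapse = ","),
        paste(colors[order(cp$labeling)], collapse = "."),
        paste(ek, collapse = ";"),
        sep = "|")
}
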