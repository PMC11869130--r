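# Action-sequence layer: stochastic depth-first-search decomposition of a
# molecule into add / connect / terminate actions, replay of action sequences
# into molecules, and enumeration of the legal next actions of a state.
#
# Actions live in tibbles with columns
#   kind        "add" | "connect" | "terminate"
#   element, charge, h_explicit   atom descriptor for "add"
#   bond        bond type for "add"/"connect"
#   attach      attachment atom index for "add" (NA for the first atom)
#   i, j        endpoints for "connect"
# Atom indices refer to construction order (1-based).

ACTION_COLS <- c("kind", "element", "charge", "h_explicit", "bond",
                 "attach", "i", "j")

# cache of utils::combn(n, 2) results, keyed by n
.combn_cache <- new.env(parent = emptyenv())
combn2 <- function(n) {
  key <- as.character(n)
  if (is.null(.combn_cache[[key]])) {
    .combn_cache[[key]] <- utils::combn(n, 2)
  }
  .combn_cache[[key]]
}

action_row <- function(kind, element = NA_character_, charge = NA_integer_,
                       h_explicit = NA_integer_, bond = NA_character_,
                       attach = NA_integer_, i = NA_integer_,
                       j = NA_integer_) {
  tibble::tibble(kind = kind, element = element,
                 charge = as.integer(charge),
                 h_explicit = as.integer(h_explicit), bond = bond,
                 attach = as.integer(attach), i = as.integer(i),
                 j = as.integer(j))
}

#' Default atom vocabulary
#'
#' The atom descriptors available to the generator when no training-derived
#' vocabulary is supplied. Following the action formalism, an added atom is
#' described by (atomic number via element symbol, formal charge, hydrogen
#' count); hydrogens are carried as pinned per-atom counts, never as graph
#' nodes. The default covers the common neutral organic descriptors plus the
#' nitro ion pair.
#'
#' @return A tibble with columns `element`, `charge`, `h_explicit`.
#' @export
default_vocabulary <- function() {
  tibble::tibble(
    element    = c("C", "C", "C", "C", "N", "N", "N", "O", "O",
                   "S", "F", "N", "O"),
    charge     = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L,
                   0L, 0L, 1L, -1L),
    h_explicit = c(3L, 2L, 1L, 0L, 2L, 1L, 0L, 1L, 0L,
                   0L, 0L, 0L, 0L)
  )
}

#' Atom vocabulary observed in a set of molecules
#'
#' Collects the distinct atom descriptors (element, formal charge,
#' explicit-H specification) occurring in the given molecules; this is the
#' vocabulary the trained model generates from.
#'
#' @param molecules A list of `mol_graph` objects.
#' @return A tibble with columns `element`, `charge`, `h_explicit`.
#' @export
atom_vocabulary <- function(molecules) {
  at <- dplyr::bind_rows(lapply(molecules, function(g)
    tibble::tibble(element = g$element, charge = g$charge,
                   h_explicit = g$h_explicit)))
  dplyr::arrange(dplyr::distinct(at), element, charge, h_explicit)
}

#' Apply one generation action to a state
#'
#' @param g The current partial `mol_graph`.
#' @param action A one-row action tibble (see [legal_actions()]).
#' @param strict Check capacity and index constraints (default `TRUE`).
#' @return The new `mol_graph`; for `"terminate"` the input graph with
#'   attribute `terminated = TRUE`.
#' @export
apply_action <- function(g, action, strict = TRUE) {
  kind <- action$kind
  if (isTRUE(attr(g, "terminated"))) stop("action after terminate")
  if (kind == "terminate") {
    attr(g, "terminated") <- TRUE
    return(g)
  }
  if (kind == "add") {
    att <- action$attach
    if (is.na(att)) {
      if (n_atoms(g) != 0) stop("first-atom add on a non-empty state")
    } else {
      if (att < 1 || att > n_atoms(g)) stop("attach index out of range")
    }
    if (strict && !is.na(att)) {
      ord <- BOND_ORDER[[action$bond]]
      occ <- occupancy(g)
      adeg_after <- aromatic_degree(g)[att] + (action$bond == "aromatic")
      if (occ[att] + ord > max_valence_eff(g)[att] +
          aromatic_slack(adeg_after, !pi_can_donate(g)[att]) + 1e-9)
        stop("add exceeds valence of attachment atom")
      hres <- ifelse(is.na(action$h_explicit), 0, action$h_explicit)
      if (ord + hres > max_valence(action$element, action$charge) + 1e-9)
        stop("add exceeds valence of new atom")
      if (action$bond == "aromatic" &&
          (!ELEMENTS[[action$element]]$aromatic_ok ||
           !ELEMENTS[[g$element[att]]]$aromatic_ok ||
           aromatic_degree(g)[att] >= 3 ||
           has_multiple_bond(g)[att]))
        stop("illegal aromatic bond")
      if (action$bond %in% c("double", "triple") &&
          aromatic_degree(g)[att] > 0)
        stop("localized multiple bond on an aromatic atom")
    }
    g <- add_atom_(g, action$element, action$charge, action$h_explicit,
                   aromatic = FALSE)
    if (!is.na(att)) g <- add_bond_(g, att, n_atoms(g), action$bond)
    return(g)
  }
  if (kind == "connect") {
    i <- action$i; j <- action$j
    if (is.na(i) || is.na(j) || i < 1 || j < 1 ||
        i > n_atoms(g) || j > n_atoms(g)) stop("connect index out of range")
    if (i == j) stop("connect self-loop")
    if (has_bond(g, i, j)) stop("duplicate bond")
    if (strict) {
      ord <- BOND_ORDER[[action$bond]]
      occ <- occupancy(g)
      adeg0 <- aromatic_degree(g)
      needs0 <- !pi_can_donate(g)
      vme <- max_valence_eff(g)
      for (a in c(i, j)) {
        adeg_after <- adeg0[a] + (action$bond == "aromatic")
        if (occ[a] + ord > vme[a] +
            aromatic_slack(adeg_after, needs0[a]) + 1e-9)
          stop("connect exceeds valence")
      }
      if (action$bond == "aromatic") {
        ad <- aromatic_degree(g)
        hm <- has_multiple_bond(g)
        if (!ELEMENTS[[g$element[i]]]$aromatic_ok ||
            !ELEMENTS[[g$element[j]]]$aromatic_ok ||
            ad[i] >= 3 || ad[j] >= 3 || hm[i] || hm[j])
          stop("illegal aromatic bond")
      }
      if (action$bond %in% c("double", "triple") &&
          any(aromatic_degree(g)[c(i, j)] > 0))
        stop("localized multiple bond on an aromatic atom")
    }
    return(add_bond_(g, i, j, action$bond))
  }
  stop("unknown action kind: ", kind)
}

#' Enumerate the candidate actions of a state and their legality
#'
#' Enumerates the full candidate action space of a partial molecule --
#' every addition (vocabulary atom x attachment atom x bond type), every
#' connection (unordered atom pair x bond type) and termination -- and marks
#' each candidate legal or not. An addition or connection is legal when both
#' touched atoms retain enough valence capacity for the new bond (aromatic
#' bonds count 1.5, require aromatic-capable elements with aromatic degree
#' < 3 so rings can still close, and never share an atom with a localized
#' double/triple bond -- quinoid motifs are written kekulized). Termination is
#' legal when the state is a complete valid molecule; if no other action is
#' legal it also becomes legal as an escape so that every reachable state has
#' at least one legal action (such escaped molecules fail validation and are
#' counted invalid downstream).
#'
#' On the empty state only first-atom additions are legal.
#'
#' @param state A `mol_graph` (possibly empty).
#' @param vocab Atom vocabulary tibble (element, charge, h_explicit);
#'   defaults to [default_vocabulary()].
#' @return A tibble of candidate actions with a logical column `legal`.
#'   The logical vector is also attached as attribute `"mask"`.
#' @export
legal_actions <- function(state, vocab = default_vocabulary()) {
  n <- n_atoms(state)
  vmax_new <- vapply(seq_len(nrow(vocab)), function(k)
    max_valence(vocab$element[k], vocab$charge[k]) -
      ifelse(is.na(vocab$h_explicit[k]), 0, vocab$h_explicit[k]),
    numeric(1))
  arom_ok_new <- vapply(vocab$element, function(e) ELEMENTS[[e]]$aromatic_ok,
                        logical(1))
  if (n == 0) {
    out <- tibble::tibble(
      kind = "add", element = vocab$element, charge = vocab$charge,
      h_explicit = vocab$h_explicit, bond = NA_character_,
      attach = NA_integer_, i = NA_integer_, j = NA_integer_,
      legal = vmax_new >= 0)
    out <- dplyr::bind_rows(out, dplyr::mutate(
      action_row("terminate"), legal = FALSE))
    attr(out, "mask") <- out$legal
    return(out)
  }
  occ <- occupancy(state)
  cap <- max_valence_eff(state) - occ
  adeg <- aromatic_degree(state)
  needs <- !pi_can_donate(state)
  hasmul <- has_multiple_bond(state)
  arom_ok_at <- vapply(state$element, function(e) ELEMENTS[[e]]$aromatic_ok,
                       logical(1))

  # additions: attach x vocab x bond type, fully vectorized
  nv <- nrow(vocab)
  grid_a <- rep(seq_len(n), each = nv * 4L)
  grid_v <- rep(rep(seq_len(nv), each = 4L), times = n)
  grid_b <- rep(BOND_TYPES, times = n * nv)
  ordv <- unname(BOND_ORDER[grid_b])
  slack_a <- aromatic_slack(adeg[grid_a] + (grid_b == "aromatic"),
                            needs[grid_a])
  add_legal <- unname(cap[grid_a] + slack_a + 1e-9 >= ordv &
    vmax_new[grid_v] >= ordv &
    (grid_b != "aromatic" |
       (arom_ok_at[grid_a] & arom_ok_new[grid_v] & adeg[grid_a] < 3 &
          !hasmul[grid_a])) &
    (!(grid_b %in% c("double", "triple")) | adeg[grid_a] == 0))

  # connections: unordered pairs x bond type
  pi_ <- integer(0); pj <- integer(0); pb <- character(0)
  con_legal <- logical(0)
  if (n >= 2) {
    pr <- combn2(n)
    pi_ <- rep(pr[1, ], each = 4L)
    pj <- rep(pr[2, ], each = 4L)
    pb <- rep(BOND_TYPES, times = ncol(pr))
    ordp <- unname(BOND_ORDER[pb])
    bm <- matrix(FALSE, n, n)
    if (n_bonds(state) > 0) bm[cbind(state$bi, state$bj)] <- TRUE
    bonded <- bm[cbind(pi_, pj)]
    slack_i <- aromatic_slack(adeg[pi_] + (pb == "aromatic"), needs[pi_])
    slack_j <- aromatic_slack(adeg[pj] + (pb == "aromatic"), needs[pj])
    con_legal <- unname(!bonded & cap[pi_] + slack_i + 1e-9 >= ordp &
      cap[pj] + slack_j + 1e-9 >= ordp &
      (pb != "aromatic" |
         (arom_ok_at[pi_] & arom_ok_at[pj] & adeg[pi_] < 3 & adeg[pj] < 3 &
            !hasmul[pi_] & !hasmul[pj])) &
      (!(pb %in% c("double", "triple")) |
         (adeg[pi_] == 0 & adeg[pj] == 0)))
  }

  na_ <- length(grid_a); nc_ <- length(pi_)
  legal <- c(add_legal, con_legal, FALSE)
  term_legal <- molecule_ok(state)
  if (!term_legal && !any(legal)) term_legal <- TRUE # escape hatch
  legal[na_ + nc_ + 1L] <- term_legal
  out <- tibble::new_tibble(list(
    kind = c(rep("add", na_), rep("connect", nc_), "terminate"),
    element = c(vocab$element[grid_v], rep(NA_character_, nc_ + 1L)),
    charge = c(vocab$charge[grid_v], rep(NA_integer_, nc_ + 1L)),
    h_explicit = c(vocab$h_explicit[grid_v], rep(NA_integer_, nc_ + 1L)),
    bond = c(grid_b, pb, NA_character_),
    attach = c(grid_a, rep(NA_integer_, nc_ + 1L)),
    i = c(rep(NA_integer_, na_), pi_, NA_integer_),
    j = c(rep(NA_integer_, na_), pj, NA_integer_),
    legal = legal), nrow = na_ + nc_ + 1L)
  attr(out, "mask") <- out$legal
  out
}

# lean adds-only enumeration (no connects/termination) used by the random
# molecule sampler; returns parallel vectors, not a tibble
enumerate_adds_ <- function(state, vocab, vmax_new, arom_ok_new) {
  n <- n_atoms(state)
  occ <- occupancy(state)
  cap <- max_valence_eff(state) - occ
  adeg <- aromatic_degree(state)
  needs <- !pi_can_donate(state)
  hasmul <- has_multiple_bond(state)
  arom_ok_at <- vapply(state$element, function(e) ELEMENTS[[e]]$aromatic_ok,
                       logical(1))
  nv <- nrow(vocab)
  grid_a <- rep(seq_len(n), each = nv * 4L)
  grid_v <- rep(rep(seq_len(nv), each = 4L), times = n)
  grid_b <- rep(BOND_TYPES, times = n * nv)
  ordv <- unname(BOND_ORDER[grid_b])
  slack_a <- aromatic_slack(adeg[grid_a] + (grid_b == "aromatic"),
                            needs[grid_a])
  legal <- unname(cap[grid_a] + slack_a + 1e-9 >= ordv &
    vmax_new[grid_v] >= ordv &
    (grid_b != "aromatic" |
       (arom_ok_at[grid_a] & arom_ok_new[grid_v] & adeg[grid_a] < 3 &
          !hasmul[grid_a])) &
    (!(grid_b %in% c("double", "triple")) | adeg[grid_a] == 0))
  list(attach = grid_a, vidx = grid_v, bond = grid_b, legal = legal)
}

#' Decompose a molecule into a stochastic action trajectory
#'
#' Runs a seeded stochastic depth-first search over the molecular graph:
#' the start atom is drawn uniformly, neighbor visit order is a uniform
#' shuffle, tree edges become `add` actions, and ring-closure edges are
#' emitted as `connect` actions at the moment the search revisits an
#' existing atom (several closures at one atom are emitted in atom-index
#' order). The final action is `terminate`. Replaying the trajectory
#' reconstructs a graph with the same canonical form.
#'
#' @param g A valid, connected, completed `mol_graph`.
#' @param seed Integer seed; `decompose()` is deterministic given `(g, seed)`.
#' @return A `fluo_trajectory`: list with `actions` (tibble) and `states`
#'   (list of `mol_graph`, `states[[k]]` being the state *before* action k).
#' @export
decompose <- function(g, seed = 1L) {
  if (!is_connected(g)) stop("cannot decompose a disconnected molecule")
  if (!molecule_ok(g)) stop("cannot decompose an invalid molecule")
  n <- n_atoms(g)
  nb <- neighbor_list(g)
  bond_of <- function(i, j) {
    ii <- min(i, j); jj <- max(i, j)
    g$btype[g$bi == ii & g$bj == jj][1]
  }
  # pin each atom's total hydrogen count into its add action: the action
  # vocabulary describes atoms as (element, charge, hydrogen count)
  ih <- implicit_h_counts(g)
  h_tot <- ifelse(is.na(g$h_explicit), ih, g$h_explicit)
  withr::with_seed(seed, {
    start <- sample.int(n, 1)
    newidx <- rep(NA_integer_, n) # original index -> construction index
    nxt <- 1L
    used <- matrix(FALSE, n, n)
    # field accumulators (one tibble built at the end)
    A <- list(kind = character(0), element = character(0),
              charge = integer(0), h_explicit = integer(0),
              bond = character(0), attach = integer(0),
              i = integer(0), j = integer(0))
    emit <- function(kind, element = NA_character_, charge = NA_integer_,
                     h = NA_integer_, bond = NA_character_,
                     attach = NA_integer_, i = NA_integer_,
                     j = NA_integer_) {
      A$kind <<- c(A$kind, kind); A$element <<- c(A$element, element)
      A$charge <<- c(A$charge, as.integer(charge))
      A$h_explicit <<- c(A$h_explicit, as.integer(h))
      A$bond <<- c(A$bond, bond); A$attach <<- c(A$attach, as.integer(attach))
      A$i <<- c(A$i, as.integer(i)); A$j <<- c(A$j, as.integer(j))
    }
    newidx[start] <- 1L; nxt <- 2L
    emit("add", g$element[start], g$charge[start], h_tot[start])
    visit <- function(u) {
      # ring closures available on entry, in atom-index order of the partner
      for (w in sort(nb[[u]])) {
        if (!is.na(newidx[w]) && !used[u, w]) {
          used[u, w] <<- TRUE; used[w, u] <<- TRUE
          emit("connect", bond = bond_of(u, w),
               i = min(newidx[u], newidx[w]), j = max(newidx[u], newidx[w]))
        }
      }
      for (w in nb[[u]][sample.int(length(nb[[u]]))]) {
        if (used[u, w]) next
        if (is.na(newidx[w])) {
          used[u, w] <<- TRUE; used[w, u] <<- TRUE
          newidx[w] <<- nxt; nxt <<- nxt + 1L
          emit("add", g$element[w], g$charge[w], h_tot[w],
               bond = bond_of(u, w), attach = newidx[u])
          visit(w)
        } else {
          # became visited while we were in a subtree: ring closure now
          used[u, w] <<- TRUE; used[w, u] <<- TRUE
          emit("connect", bond = bond_of(u, w),
               i = min(newidx[u], newidx[w]), j = max(newidx[u], newidx[w]))
        }
      }
    }
    visit(start)
    emit("terminate")
    actions <- tibble::new_tibble(A, nrow = length(A$kind))
  })
  states <- vector("list", nrow(actions))
  st <- mol_graph()
  for (k in seq_len(nrow(actions))) {
    states[[k]] <- st
    st <- apply_action(st, actions[k, ], strict = FALSE)
  }
  structure(list(actions = actions, states = states, final = st),
            class = "fluo_trajectory")
}

#' @export
print.fluo_trajectory <- function(x, ...) {
  cat("<fluo_trajectory> ", nrow(x$actions), " actions -> ",
      n_atoms(x$final), " atoms\n", sep = "")
  invisible(x)
}

#' Replay an action sequence into a molecule
#'
#' @param t A `fluo_trajectory`, or a tibble of actions (columns as produced
#'   by [decompose()] / [legal_actions()]).
#' @param scaffold Optional `mol_graph` used as the initial state.
#' @return The final `mol_graph`. Errors on out-of-range indices, duplicate
#'   bonds, or actions after `terminate`.
#' @export
replay <- function(t, scaffold = NULL) {
  actions <- if (inherits(t, "fluo_trajectory")) t$actions else t
  st <- if (is.null(scaffold)) mol_graph() else scaffold
  for (k in seq_len(nrow(actions))) {
    st <- apply_action(st, actions[k, ], strict = FALSE)
  }
  st
}

#' Serialize / read a trajectory as JSON lines
#'
#' One line per step holding the state (as a SMILES fragment, empty string
#' for the empty state) and the tagged action record.
#'
#' @param t A `fluo_trajectory`.
#' @param path File path.
#' @return `write_trajectory_jsonl()` returns `path` invisibly;
#'   `read_trajectory_jsonl()` returns a tibble of actions with a
#'   `state_smiles` column.
#' @export
write_trajectory_jsonl <- function(t, path) {
  lines <- vapply(seq_len(nrow(t$actions)), function(k) {
    st <- t$states[[k]]
    smi <- if (n_atoms(st) == 0) "" else write_structure(st)
    jsonlite::toJSON(c(list(state = smi),
                       as.list(t$actions[k, ])),
                     auto_unbox = TRUE, na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trajectory_jsonl
#' @export
read_trajectory_jsonl <- function(path) {
  recs <- lapply(readLines(path), jsonlite::fromJSON)
  dplyr::bind_rows(lapply(recs, function(r) {
    r <- lapply(r, function(v) if (is.null(v)) NA else v)
    tibble::tibble(state_smiles = r$state, kind = r$kind,
                   element = as.character(r$element),
                   charge = as.integer(r$charge),
                   h_explicit = as.integer(r$h_explicit),
                   bond = as.character(r$bond),
                   attach = as.integer(r$attach),
                   i = as.integer(r$i), j = as.integer(r$j))
  }))
}
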