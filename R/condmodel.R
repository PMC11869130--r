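# Conditional action-probability model.
#
# The model scores every legal next action of a partial molecule under a
# target condition (seven optical properties + solvent) and normalizes with
# a masked softmax. Scoring is bilinear: score(s, a | c) = phi(s, a)' W
# psi(c), where phi collects structural action/state features (graph
# invariants plus construction-order positional features, so the loss is
# invariant under relabeling of the training molecule) and psi is the
# encoded condition. Training minimizes the teacher-forcing negative
# log-likelihood of stochastic-DFS decompositions with the Adam optimizer,
# drawing a fresh decomposition of each molecule every epoch as data
# augmentation.

PROPERTY_NAMES <- c("lambda_abs", "sigma_abs", "log_eps", "lambda_emi",
                    "sigma_emi", "phi", "tau")

#' Validate a target condition
#'
#' A condition is the seven target optical properties plus a solvent key:
#' `lambda_abs` (nm), `sigma_abs` (cm-1), `log_eps` (log10 of the molar
#' extinction coefficient), `lambda_emi` (nm), `sigma_emi` (cm-1), `phi`
#' (quantum yield, 0..1), `tau` (ns), `solvent`.
#'
#' @param x A named list or one-row data frame with the fields above
#'   (optionally `dielectric` for solvents outside the solvent table).
#' @return A validated named list.
#' @export
as_condition <- function(x) {
  x <- as.list(x)
  missing <- setdiff(c(PROPERTY_NAMES, "solvent"), names(x))
  if (length(missing) > 0) {
    stop("condition is missing fields: ", paste(missing, collapse = ", "))
  }
  vals <- unlist(x[PROPERTY_NAMES])
  if (!all(is.finite(vals))) stop("condition properties must be finite")
  if (x$phi < 0 || x$phi > 1) stop("phi must lie in [0, 1]")
  if (x$lambda_abs <= 0 || x$lambda_emi <= 0) stop("wavelengths must be > 0")
  if (x$sigma_abs <= 0 || x$sigma_emi <= 0) stop("bandwidths must be > 0")
  if (x$tau <= 0) stop("tau must be > 0")
  x[c(PROPERTY_NAMES, "solvent",
      intersect("dielectric", names(x)))]
}

#' Fit condition-normalization statistics
#'
#' Per-property mean and standard deviation over the training records, plus
#' the same for the solvent dielectric; stored with the model checkpoint and
#' used to z-score conditions.
#'
#' @param db A tibble of training records with the seven property columns
#'   and a `solvent` column.
#' @param solvents Solvent table (see [default_solvents()]).
#' @return A list with numeric vectors `mean` and `sd`.
#' @export
fit_condition_stats <- function(db, solvents = default_solvents()) {
  stopifnot(all(PROPERTY_NAMES %in% names(db)))
  diel <- solvents$dielectric[match(db$solvent, solvents$solvent)]
  m <- c(vapply(PROPERTY_NAMES, function(p) mean(db[[p]], na.rm = TRUE),
                numeric(1)), dielectric = mean(diel, na.rm = TRUE))
  s <- c(vapply(PROPERTY_NAMES, function(p) stats::sd(db[[p]], na.rm = TRUE),
                numeric(1)), dielectric = stats::sd(diel, na.rm = TRUE))
  s[!is.finite(s) | s < 1e-12] <- 1
  list(mean = m, sd = s)
}

#' Encode a condition as a numeric vector
#'
#' The seven properties are z-scored with the training statistics and
#' concatenated with the solvent representation: an indicator over the known
#' solvent table (whose learned weight columns act as a per-solvent
#' embedding) plus the z-scored dielectric constant as a numeric feature.
#' For a solvent outside the table the indicator block is zero and the
#' dielectric carries all solvent information (the documented fallback);
#' with `fallback = FALSE` an unknown solvent is an error.
#'
#' @param condition A condition (see [as_condition()]).
#' @param stats Normalization statistics from [fit_condition_stats()].
#' @param solvents Solvent table.
#' @param fallback Allow unknown solvents via the dielectric-only fallback.
#' @return A named numeric vector of length `7 + nrow(solvents) + 1`.
#' @export
encode_condition <- function(condition, stats, solvents = default_solvents(),
                             fallback = TRUE) {
  condition <- as_condition(condition)
  z <- vapply(PROPERTY_NAMES, function(p)
    (condition[[p]] - stats$mean[[p]]) / stats$sd[[p]], numeric(1))
  k <- match(condition$solvent, solvents$solvent)
  onehot <- as.numeric(seq_len(nrow(solvents)) == ifelse(is.na(k), 0L, k))
  names(onehot) <- paste0("solvent_", solvents$solvent)
  if (is.na(k)) {
    if (!fallback) stop("unknown solvent: ", condition$solvent)
    diel <- condition$dielectric
    if (is.null(diel)) {
      stop("unknown solvent '", condition$solvent,
           "' needs an explicit dielectric for the fallback encoding")
    }
  } else {
    diel <- solvents$dielectric[k]
  }
  c(z, onehot,
    dielectric = (diel - stats$mean[["dielectric"]]) / stats$sd[["dielectric"]])
}

# Feature construction ---------------------------------------------------

model_pars <- function(vocab, pos_slots = 24L, size_slots = 24L) {
  list(vocab = vocab, pos_slots = as.integer(pos_slots),
       size_slots = as.integer(size_slots))
}

vocab_labels <- function(vocab) {
  paste0("add_vocab_", vocab$element,
         ifelse(vocab$charge == 0, "", sprintf("%+d", vocab$charge)),
         "H", vocab$h_explicit)
}
vlab_first <- function(pars) vocab_labels(pars$vocab)[1]

feature_names <- function(pars) {
  V <- nrow(pars$vocab); P <- pars$pos_slots; S <- pars$size_slots
  vlab <- vocab_labels(pars$vocab)
  c("kind_add", "kind_connect", "kind_terminate",
    vlab,
    "add_is_first", paste0("first_", vlab),
    paste0("add_bond_", BOND_TYPES), "add_bond_order", "add_extends_conj",
    paste0("add_attach_el_", names(ELEMENTS)),
    "add_attach_aromatic", "add_attach_degree", "add_attach_occupancy",
    "add_attach_is_last", "add_attach_relpos",
    paste0("add_attach_pos_", seq_len(P)),
    paste0("add_attach_occ_", 0:12), paste0("add_attach_deg_", 0:4),
    as.vector(outer(vlab, 0:12, function(v, o) paste0(v, "_occ", o))),
    as.vector(outer(paste0("bond_", BOND_TYPES), 0:12,
                    function(b, o) paste0(b, "_occ", o))),
    as.vector(outer(vlab, seq_len(P), function(v, q) paste0(v, "_pos", q))),
    paste0("con_bond_", BOND_TYPES),
    paste0("con_ring_", c("3", "4", "5", "6", "7p")),
    "con_both_aromatic", "con_touches_last",
    paste0("con_pos_i_", seq_len(P)), paste0("con_pos_j_", seq_len(P)),
    "term_bias", "term_natoms", "term_nbonds", "term_nrings",
    "term_naromatic", "term_nconj", "term_donors", "term_acceptors",
    "term_frac_c", "term_nhetero",
    paste0("term_size_", seq_len(S)))
}

# Feature matrix for candidate actions in `state`; `rows` selects a subset
# of `cand` (by index) without paying for a tibble subset.
featurize_actions <- function(state, cand, pars, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(cand))
  kind <- cand$kind[rows]; element <- cand$element[rows]
  charge <- cand$charge[rows]; hx <- cand$h_explicit[rows]
  bondv <- cand$bond[rows]; attach <- cand$attach[rows]
  iv <- cand$i[rows]; jv <- cand$j[rows]
  nm <- feature_names(pars)
  p <- length(nm)
  nr <- length(rows)
  M <- matrix(0, nr, p, dimnames = list(NULL, nm))
  n <- n_atoms(state)
  V <- nrow(pars$vocab); P <- pars$pos_slots; S <- pars$size_slots

  is_add <- kind == "add"
  is_con <- kind == "connect"
  is_term <- kind == "terminate"
  M[, "kind_add"] <- is_add
  M[, "kind_connect"] <- is_con
  M[, "kind_terminate"] <- is_term

  if (n > 0) {
    occ <- occupancy(state)
    deg <- atom_degree(state)
    multi <- state$btype %in% c("double", "triple", "aromatic")
    pi_atom <- rep(FALSE, n)
    pi_atom[unique(c(state$bi[multi], state$bj[multi]))] <- TRUE
  }

  if (any(is_add)) {
    a <- which(is_add)
    vkey <- paste(element[a], charge[a], hx[a])
    vidx <- match(vkey, paste(pars$vocab$element, pars$vocab$charge,
                              pars$vocab$h_explicit))
    known <- !is.na(vidx)
    M[cbind(a[known], 3L + vidx[known])] <- 1
    bo <- bondv[a]
    hasb <- !is.na(bo)
    abase <- which(nm == "add_bond_single") - 1L
    M[cbind(a[hasb], abase + match(bo[hasb], BOND_TYPES))] <- 1
    M[a[hasb], "add_bond_order"] <- unname(BOND_ORDER[bo[hasb]])
    att <- attach[a]
    hasa <- !is.na(att)
    if (any(!hasa)) {
      # first-atom additions get their own vocabulary block so the choice of
      # start atom does not compete with ordinary additions in later states
      M[a[!hasa], "add_is_first"] <- 1
      fbase <- which(nm == "add_is_first")
      M[cbind(a[!hasa & known], fbase + vidx[!hasa & known])] <- 1
    }
    if (any(hasa)) {
      ai <- a[hasa]; at <- att[hasa]
      M[ai, "add_extends_conj"] <-
        as.numeric(bo[hasa] %in% c("double", "triple", "aromatic") |
                   pi_atom[at])
      el_idx <- match(state$element[at], names(ELEMENTS))
      base <- which(nm == "add_attach_el_B") - 1L
      M[cbind(ai, base + el_idx)] <- 1
      M[ai, "add_attach_aromatic"] <- as.numeric(state$aromatic[at])
      M[ai, "add_attach_degree"] <- deg[at] / 4
      M[ai, "add_attach_occupancy"] <- occ[at] / 4
      M[ai, "add_attach_is_last"] <- as.numeric(at == n)
      M[ai, "add_attach_relpos"] <- at / n
      posb <- which(nm == "add_attach_pos_1") - 1L
      M[cbind(ai, posb + pmin(at, P))] <- 1
      oslot <- pmin(round(occ[at] * 2), 12L) # occupancy in half-bond units
      occb <- which(nm == "add_attach_occ_0") - 1L
      M[cbind(ai, occb + oslot + 1L)] <- 1
      degb <- which(nm == "add_attach_deg_0") - 1L
      M[cbind(ai, degb + pmin(deg[at], 4L) + 1L)] <- 1
      # conjunctions with the attachment context: which atom type / bond is
      # appropriate depends on how occupied the attachment site already is,
      # and a linear score over marginal features cannot express that
      vob <- which(nm == paste0(vlab_first(pars), "_occ0")) - 1L
      ka <- known[hasa]
      M[cbind(ai[ka], vob + oslot[ka] * V + vidx[hasa][ka])] <- 1
      bob <- which(nm == "bond_single_occ0") - 1L
      M[cbind(ai, bob + oslot * 4L + match(bo[hasa], BOND_TYPES))] <- 1
      vpb <- which(nm == paste0(vlab_first(pars), "_pos1")) - 1L
      M[cbind(ai[ka], vpb + (pmin(at, P)[ka] - 1L) * V + vidx[hasa][ka])] <- 1
    }
  }

  if (any(is_con)) {
    cidx <- which(is_con)
    bo <- bondv[cidx]
    bbase <- which(nm == "con_bond_single") - 1L
    M[cbind(cidx, bbase + match(bo, BOND_TYPES))] <- 1
    ci <- iv[cidx]; cj <- jv[cidx]
    d <- pair_distances(state, ci, cj)
    ring <- d + 1L
    rbase <- which(nm == "con_ring_3") - 1L
    rslot <- pmin(pmax(ring, 3L), 7L) - 2L # 3,4,5,6,7+ -> 1..5
    M[cbind(cidx, rbase + rslot)] <- 1
    M[cidx, "con_both_aromatic"] <-
      as.numeric(state$aromatic[ci] & state$aromatic[cj])
    M[cidx, "con_touches_last"] <- as.numeric(ci == n | cj == n)
    pib <- which(nm == "con_pos_i_1") - 1L
    pjb <- which(nm == "con_pos_j_1") - 1L
    M[cbind(cidx, pib + pmin(ci, P))] <- 1
    M[cbind(cidx, pjb + pmin(cj, P))] <- 1
  }

  if (any(is_term)) {
    t_ <- which(is_term)
    M[t_, "term_bias"] <- 1
    if (n > 0) {
      conj <- sum(multi | (state$btype == "single" &
                             pi_atom[state$bi] & pi_atom[state$bj]))
      M[t_, "term_natoms"] <- n / 10
      M[t_, "term_nbonds"] <- n_bonds(state) / 10
      M[t_, "term_nrings"] <- (n_bonds(state) - n + 1) / 3
      M[t_, "term_naromatic"] <- sum(state$aromatic) / 10
      M[t_, "term_nconj"] <- conj / 10
      M[t_, "term_donors"] <- count_donor_groups(state)
      M[t_, "term_acceptors"] <- count_acceptor_groups(state)
      M[t_, "term_frac_c"] <- mean(state$element == "C")
      M[t_, "term_nhetero"] <- sum(state$element %in% c("N", "O")) / 5
      sbase <- which(nm == "term_size_1") - 1L
      M[t_, sbase + pmin(n, S)] <- 1
    }
  }
  M
}

# shortest bond-path distance between atom pairs (for ring-size features)
pair_distances <- function(g, is, js) {
  n <- n_atoms(g)
  nb <- neighbor_list(g)
  out <- integer(length(is))
  for (k in seq_along(is)) {
    src <- is[k]; dst <- js[k]
    dist <- rep(NA_integer_, n); dist[src] <- 0L
    frontier <- src
    while (length(frontier) > 0 && is.na(dist[dst])) {
      nxt <- unique(unlist(nb[frontier]))
      nxt <- nxt[is.na(dist[nxt])]
      if (length(nxt) == 0) break
      dist[nxt] <- dist[frontier[1]] + 1L
      frontier <- nxt
    }
    out[k] <- ifelse(is.na(dist[dst]), 99L, dist[dst])
  }
  out
}

# Model ------------------------------------------------------------------

#' Model configuration
#'
#' @param epochs Number of training epochs (a fresh stochastic decomposition
#'   of every molecule is drawn each epoch).
#' @param learning_rate Adam step size.
#' @param batch_size Molecules per gradient update.
#' @param seed Master RNG seed for decomposition draws and shuffling.
#' @param pos_slots,size_slots Number of construction-order position /
#'   molecule-size indicator slots in the feature map.
#' @param temperature Sampling temperature used at generation time.
#' @param augment Draw a fresh stochastic decomposition of every molecule
#'   each epoch (default). With `FALSE` the decomposition of each molecule
#'   is fixed across epochs (useful for overfitting diagnostics).
#' @return A list of class `fluogen_config`.
#' @export
model_config <- function(epochs = 4L, learning_rate = 0.08, batch_size = 16L,
                         seed = 1L, pos_slots = 24L, size_slots = 24L,
                         temperature = 1, augment = TRUE) {
  stopifnot(epochs >= 1, learning_rate > 0, batch_size >= 1,
            pos_slots >= 1, size_slots >= 1, temperature > 0)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 pos_slots = as.integer(pos_slots),
                 size_slots = as.integer(size_slots),
                 temperature = temperature, augment = isTRUE(augment)),
            class = "fluogen_config")
}

derive_seed <- function(seed, ...) {
  key <- paste(seed, ..., sep = "/")
  abs(digest::digest2int(key)) %% 2147483646L + 1L
}

#' Train the conditional generator
#'
#' Teacher forcing on stochastic-DFS action trajectories: each epoch draws a
#' fresh decomposition of every training molecule, and the model is fit to
#' maximize the log-probability of each recorded action among the legal
#' actions of its state, conditioned on the molecule's own measured
#' properties and solvent.
#'
#' @param db A tibble with a `smiles` column, the seven property columns
#'   (`lambda_abs`, `sigma_abs`, `log_eps`, `lambda_emi`, `sigma_emi`,
#'   `phi`, `tau`) and a `solvent` column; one row per molecule/solvent
#'   pair.
#' @param config A [model_config()].
#' @param solvents Solvent table (see [default_solvents()]).
#' @param quiet Suppress the per-epoch loss message.
#' @return A fitted model of class `fluogen_model`, with the training-loss
#'   trace in `$history`.
#' @export
train_generator <- function(db, config = model_config(),
                            solvents = default_solvents(), quiet = FALSE) {
  if (nrow(db) == 0) stop("empty training database")
  stopifnot(all(c("smiles", PROPERTY_NAMES, "solvent") %in% names(db)))
  mols <- lapply(db$smiles, parse_structure)
  vocab <- atom_vocabulary(lapply(mols, function(g) {
    # vocabulary is built from pinned-hydrogen descriptors
    ih <- implicit_h_counts(g)
    g$h_explicit <- ifelse(is.na(g$h_explicit), ih, g$h_explicit)
    g
  }))
  stats <- fit_condition_stats(db, solvents)
  pars <- model_pars(vocab, config$pos_slots, config$size_slots)
  pn <- feature_names(pars)
  qn <- c("bias", PROPERTY_NAMES, paste0("solvent_", solvents$solvent),
          "dielectric")
  p <- length(pn); q <- length(qn)
  W <- matrix(0, p, q, dimnames = list(pn, qn))
  mA <- matrix(0, p, q); vA <- matrix(0, p, q)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; tstep <- 0

  psi_all <- t(vapply(seq_len(nrow(db)), function(r)
    c(bias = 1, encode_condition(as.list(db[r, c(PROPERTY_NAMES, "solvent")]),
                                 stats, solvents)), numeric(q)))

  history <- tibble::tibble(epoch = integer(0), nll = numeric(0))
  n_mol <- nrow(db)
  for (epoch in seq_len(config$epochs)) {
    order <- withr::with_seed(derive_seed(config$seed, "shuffle", epoch),
                              sample.int(n_mol))
    tot_loss <- 0; tot_steps <- 0L
    batches <- split(order, ceiling(seq_along(order) / config$batch_size))
    for (bt in batches) {
      G <- matrix(0, p, q)
      b_steps <- 0L
      for (r in bt) {
        dfs_seed <- if (config$augment) {
          derive_seed(config$seed, "dfs", epoch, r)
        } else {
          derive_seed(config$seed, "dfs", r)
        }
        traj <- decompose(mols[[r]], dfs_seed)
        acts <- traj$actions
        psi <- psi_all[r, ]
        wpsi <- W %*% psi
        for (k in seq_len(nrow(acts))) {
          state <- traj$states[[k]]
          cand <- legal_actions(state, vocab)
          leg <- which(cand$legal)
          Phi <- featurize_actions(state, cand, pars, rows = leg)
          sc <- as.numeric(Phi %*% wpsi)
          sc <- sc - max(sc)
          pr <- exp(sc); pr <- pr / sum(pr)
          y <- match_action_idx(cand, leg,
                                lapply(acts, `[`, k))
          if (is.na(y)) stop("recorded action not in legal set (internal)")
          loss_k <- -log(pr[y])
          if (!is.finite(loss_k)) stop("non-finite training loss")
          tot_loss <- tot_loss + loss_k
          gsc <- pr; gsc[y] <- gsc[y] - 1
          G <- G + tcrossprod(crossprod(Phi, gsc), psi)
          b_steps <- b_steps + 1L
        }
      }
      if (b_steps > 0) {
        G <- G / b_steps
        tstep <- tstep + 1
        mA <- b1 * mA + (1 - b1) * G
        vA <- b2 * vA + (1 - b2) * G * G
        mh <- mA / (1 - b1^tstep); vh <- vA / (1 - b2^tstep)
        W <- W - config$learning_rate * mh / (sqrt(vh) + eps)
      }
      tot_steps <- tot_steps + b_steps
    }
    nll <- tot_loss / tot_steps
    history <- dplyr::bind_rows(history,
                                tibble::tibble(epoch = epoch, nll = nll))
    if (!quiet) message(sprintf("epoch %d/%d  mean NLL %.4f",
                                epoch, config$epochs, nll))
  }
  structure(list(W = W, vocab = vocab, solvents = solvents, stats = stats,
                 config = config, pars = pars, history = history),
            class = "fluogen_model")
}

match_action_idx <- function(cand, leg, act) {
  key <- paste(cand$kind[leg], cand$element[leg], cand$charge[leg],
               cand$h_explicit[leg], cand$bond[leg], cand$attach[leg],
               cand$i[leg], cand$j[leg])
  match(paste(act$kind, act$element, act$charge, act$h_explicit, act$bond,
              act$attach, act$i, act$j), key)
}

match_action <- function(cand, action) {
  key <- function(a) paste(a$kind, a$element, a$charge, a$h_explicit, a$bond,
                           a$attach, pmin(a$i, a$j), pmax(a$i, a$j))
  match(key(action), key(cand))
}

#' @export
print.fluogen_model <- function(x, ...) {
  cat("<fluogen_model> ", nrow(x$W), " features x ", ncol(x$W),
      " condition slots; vocab ", nrow(x$vocab), " atoms; ",
      nrow(x$history), " epochs (final NLL ",
      sprintf("%.4f", utils::tail(x$history$nll, 1)), ")\n", sep = "")
  invisible(x)
}

#' Action distribution of a state under a condition
#'
#' Masked softmax of the model's bilinear scores over the legal actions of
#' `state`; illegal actions carry exactly zero probability.
#'
#' @param state A partial `mol_graph`.
#' @param condition A condition (see [as_condition()]).
#' @param model A fitted `fluogen_model`.
#' @param temperature Softmax temperature (default from the model config).
#' @return The candidate-action tibble of [legal_actions()] with a `prob`
#'   column summing to 1 over legal rows.
#' @export
action_distribution <- function(state, condition, model,
                                temperature = model$config$temperature) {
  cand <- legal_actions(state, model$vocab)
  leg <- which(cand$legal)
  stopifnot(length(leg) > 0)
  psi <- c(bias = 1, encode_condition(condition, model$stats, model$solvents))
  Phi <- featurize_actions(state, cand, model$pars, rows = leg)
  sc <- as.numeric(Phi %*% (model$W %*% psi)) / temperature
  sc <- sc - max(sc)
  pr <- exp(sc); pr <- pr / sum(pr)
  cand$prob <- 0
  cand$prob[leg] <- pr
  cand
}

# Checkpoint I/O ---------------------------------------------------------

num_to_chr <- function(x) sprintf("%.17g", x)

#' Save / load a model checkpoint
#'
#' Checkpoints are a single JSON file holding the weight matrix (full
#' IEEE precision), the configuration, atom vocabulary, solvent table and
#' normalization statistics; loading restores the model bit-identically.
#'
#' @param model A `fluogen_model`.
#' @param path File path (`.json`).
#' @return `write_checkpoint()` returns `path` invisibly;
#'   `read_checkpoint()` returns the restored `fluogen_model`.
#' @export
write_checkpoint <- function(model, path) {
  obj <- list(
    package = "fluogen", format = 1L,
    W = list(dim = dim(model$W), dimnames = dimnames(model$W),
             values = num_to_chr(as.numeric(model$W))),
    vocab = model$vocab,
    solvents = model$solvents,
    stats = list(
      mean = as.list(stats::setNames(num_to_chr(model$stats$mean),
                                     names(model$stats$mean))),
      sd = as.list(stats::setNames(num_to_chr(model$stats$sd),
                                   names(model$stats$sd)))),
    config = unclass(model$config),
    pars = list(pos_slots = model$pars$pos_slots,
                size_slots = model$pars$size_slots),
    history = model$history
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  W <- matrix(as.numeric(obj$W$values), obj$W$dim[1], obj$W$dim[2],
              dimnames = obj$W$dimnames)
  stats <- list(
    mean = stats::setNames(as.numeric(unlist(obj$stats$mean)),
                           names(obj$stats$mean)),
    sd = stats::setNames(as.numeric(unlist(obj$stats$sd)),
                         names(obj$stats$sd)))
  vocab <- tibble::as_tibble(obj$vocab)
  vocab$charge <- as.integer(vocab$charge)
  vocab$h_explicit <- as.integer(vocab$h_explicit)
  cfg <- do.call(model_config, obj$config)
  structure(list(
    W = W, vocab = vocab, solvents = tibble::as_tibble(obj$solvents),
    stats = stats, config = cfg,
    pars = model_pars(vocab, obj$pars$pos_slots, obj$pars$size_slots),
    history = tibble::as_tibble(obj$history)),
    class = "fluogen_model")
}

# broom-style methods ----------------------------------------------------

#' Tidy a fitted generator model
#'
#' @param x A `fluogen_model`.
#' @param ... Unused.
#' @return A long tibble of weights: one row per (feature, condition slot).
#' @export
tidy.fluogen_model <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$W, responseName = "weight",
                                        stringsAsFactors = FALSE)) |>
    stats::setNames(c("feature", "condition", "weight"))
}

#' @rdname tidy.fluogen_model
#' @param x A `fluogen_model`.
#' @return `glance()`: a one-row tibble of fit summaries.
#' @export
glance.fluogen_model <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$W), n_condition_slots = ncol(x$W),
    n_parameters = length(x$W), vocab_size = nrow(x$vocab),
    epochs = nrow(x$history),
    initial_nll = x$history$nll[1],
    final_nll = utils::tail(x$history$nll, 1))
}
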