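# Evaluation stack: validity / uniqueness / novelty, fraction of molecules
# meeting the target property windows, Stokes shift, Crippen-type log P,
# degree of conjugation, fingerprint chemical-space embedding, and
# reference-set lookup.

#' Validity, uniqueness and novelty of a generated set
#'
#' Conventions (also recorded in the returned object): validity is the
#' fraction of generated structures that parse, pass valence validation and
#' are connected; uniqueness is the number of distinct canonical forms among
#' the valid molecules divided by the number of valid molecules; novelty is
#' the fraction of those distinct canonical forms not present in the
#' training set.
#'
#' @param generated Generated structures: a `fluogen_generation` tibble, or
#'   a character vector of SMILES.
#' @param training_set Character vector of canonical forms of the training
#'   molecules.
#' @return A one-row tibble of class `fluogen_metrics`: `n_generated`,
#'   `n_valid`, `validity`, `uniqueness`, `novelty`, plus the convention
#'   strings. The distinct canonical forms are attached as attribute
#'   `"unique_canonical"`.
#' @export
generation_metrics <- function(generated, training_set = character(0)) {
  if (inherits(generated, "fluogen_generation") ||
      (is.data.frame(generated) && "smiles" %in% names(generated))) {
    n_gen <- nrow(generated)
    valid <- generated$valid
    canon <- generated$canonical[valid]
  } else {
    stopifnot(is.character(generated))
    if (length(generated) == 0) stop("empty generated set")
    parsed <- lapply(generated, function(s)
      tryCatch(parse_structure(s), error = function(e) NULL))
    valid <- vapply(parsed, function(g)
      !is.null(g) && molecule_ok(g), logical(1))
    n_gen <- length(generated)
    canon <- if (any(valid)) canonical_form(generated[valid]) else character(0)
  }
  if (n_gen == 0) stop("empty generated set")
  n_valid <- sum(valid)
  uniq <- unique(canon)
  novel <- setdiff(uniq, training_set)
  out <- tibble::tibble(
    n_generated = n_gen, n_valid = n_valid,
    validity = n_valid / n_gen,
    uniqueness = ifelse(n_valid == 0, NA_real_, length(uniq) / n_valid),
    novelty = ifelse(length(uniq) == 0, NA_real_,
                     length(novel) / length(uniq)),
    uniqueness_convention = "distinct canonical / valid",
    novelty_convention = "distinct canonical not in training / distinct canonical")
  attr(out, "unique_canonical") <- uniq
  class(out) <- c("fluogen_metrics", class(out))
  out
}

#' Property windows for target matching
#'
#' Per-property half-width tolerances deciding whether a generated molecule
#' meets the target (the windows stand in for the error ranges of a
#' property predictor and are configuration, not measured values).
#' `tau` is relative (fraction of the target value); the others absolute.
#'
#' @param lambda_abs,lambda_emi nm. @param sigma_abs,sigma_emi cm-1.
#' @param log_eps log10 units. @param phi Quantum-yield units.
#' @param tau_rel Relative lifetime half-width.
#' @return A named list of class `fluogen_window`.
#' @export
property_window <- function(lambda_abs = 25, sigma_abs = 700, log_eps = 0.35,
                            lambda_emi = 25, sigma_emi = 700, phi = 0.12,
                            tau_rel = 0.5) {
  w <- list(lambda_abs = lambda_abs, sigma_abs = sigma_abs,
            log_eps = log_eps, lambda_emi = lambda_emi,
            sigma_emi = sigma_emi, phi = phi, tau_rel = tau_rel)
  stopifnot(all(unlist(w) > 0))
  structure(w, class = "fluogen_window")
}

#' Fraction of molecules meeting the target properties
#'
#' Scores every molecule with the property oracle in the target's solvent
#' and counts it as meeting the target if and only if all seven properties
#' lie simultaneously within `target +/- window` (joint criterion);
#' per-property hit rates are returned for diagnostics. Molecules the
#' oracle fails on are excluded and listed.
#'
#' @param mols Character vector of SMILES (or list of `mol_graph`).
#' @param oracle A `function(molecule, solvent)` property oracle.
#' @param target The target condition.
#' @param window A [property_window()].
#' @return A list: `fraction`, `members` (tibble of hits with their scored
#'   properties), `per_property` (named hit rates), `n_scored`, `failed`.
#' @export
fraction_within_target <- function(mols, oracle, target,
                                   window = property_window()) {
  target <- as_condition(target)
  if (inherits(mols, "mol_graph")) mols <- list(mols)
  scored <- vector("list", length(mols))
  failed <- integer(0)
  for (k in seq_along(mols)) {
    val <- tryCatch(oracle(mols[[k]], target$solvent),
                    error = function(e) NULL)
    if (is.null(val)) failed <- c(failed, k) else scored[[k]] <- val
  }
  ok <- setdiff(seq_along(mols), failed)
  if (length(ok) == 0) {
    return(list(fraction = NA_real_, members = tibble::tibble(),
                per_property = NULL, n_scored = 0L, failed = failed))
  }
  props <- dplyr::bind_rows(scored[ok])
  hw <- function(p) if (p == "tau") window$tau_rel * target$tau else window[[p]]
  inside <- vapply(PROPERTY_NAMES, function(p)
    abs(props[[p]] - target[[p]]) <= hw(p), logical(length(ok)))
  inside <- matrix(inside, nrow = length(ok))
  colnames(inside) <- PROPERTY_NAMES
  hit <- rowSums(inside) == length(PROPERTY_NAMES)
  members <- dplyr::bind_cols(
    tibble::tibble(index = ok[hit],
                   smiles = vapply(mols[ok[hit]], function(m)
                     if (is.character(m)) m else write_structure(m),
                     character(1))),
    props[hit, ])
  list(fraction = mean(hit), members = members,
       per_property = colMeans(inside), n_scored = length(ok),
       failed = failed)
}

#' Stokes shift
#'
#' The difference between emission and absorption peak positions,
#' `lambda_emi - lambda_abs` (nm). Negative values are physically suspect
#' and flagged in the `"flagged_negative"` attribute.
#'
#' @param lambda_emi,lambda_abs Peak positions in nm (vectorized).
#' @return Numeric vector of shifts (nm).
#' @examples
#' stokes_shift(550, 380) # 170
#' @export
stokes_shift <- function(lambda_emi, lambda_abs) {
  stopifnot(all(lambda_emi > 0), all(lambda_abs > 0))
  out <- lambda_emi - lambda_abs
  attr(out, "flagged_negative") <- which(out < 0)
  out
}

#' Degree of conjugation
#'
#' The number of bonds connecting the two farthest atoms within the
#' conjugated backbone: for each conjugated component, all-pairs shortest
#' paths restricted to the component's bonds; the DOC is the maximum over
#' components (0 for molecules without conjugated bonds). Ties are broken
#' by the lowest atom-index pair.
#'
#' @param g A valid `mol_graph` (or SMILES).
#' @return A list: `doc` (integer bond count), `pair` (the achieving atom
#'   indices), `component` (which conjugated component).
#' @examples
#' degree_of_conjugation(parse_structure("c1ccccc1"))$doc      # 3
#' degree_of_conjugation(parse_structure("C=CC=C"))$doc        # 3
#' @export
degree_of_conjugation <- function(g) {
  if (is.character(g)) g <- parse_structure(g)
  comps <- conjugated_components(g)
  if (length(comps) == 0) {
    return(list(doc = 0L, pair = NULL, component = NA_integer_))
  }
  best <- list(doc = -1L, pair = NULL, component = NA_integer_)
  for (ci in seq_along(comps)) {
    bidx <- comps[[ci]]
    el <- cbind(g$bi[bidx], g$bj[bidx])
    verts <- sort(unique(as.vector(el)))
    ig <- igraph::graph_from_edgelist(
      matrix(match(el, verts), ncol = 2), directed = FALSE)
    d <- igraph::distances(ig)
    dmax <- max(d[is.finite(d)])
    if (dmax > best$doc) {
      w <- which(d == dmax, arr.ind = TRUE)
      w <- w[w[, 1] < w[, 2], , drop = FALSE]
      pairs <- cbind(verts[w[, 1]], verts[w[, 2]])
      o <- order(pairs[, 1], pairs[, 2])
      best <- list(doc = as.integer(dmax), pair = pairs[o[1], ],
                   component = ci)
    }
  }
  best
}

#' Crippen-type log P
#'
#' Octanol--water partition coefficient estimated by the atom-contribution
#' method (computed through the cheminformatics backend); deterministic.
#'
#' @param x A character vector of SMILES, or a `mol_graph`.
#' @return Numeric vector of log P values.
#' @export
logp <- function(x) {
  if (inherits(x, "mol_graph")) x <- write_structure(x)
  stopifnot(is.character(x), length(x) >= 1)
  sdf <- ChemmineOB::convertFormat("SMI", "SDF", paste(x, collapse = "\n"))
  sdfset <- ChemmineR::read.SDFset(ChemmineR::read.SDFstr(
    strsplit(sdf, "\n", fixed = TRUE)[[1]]))
  pr <- ChemmineR::propOB(sdfset)
  if (nrow(pr) != length(x) || any(!is.finite(pr$logP))) {
    bad <- if (nrow(pr) == length(x)) which(!is.finite(pr$logP)) else NA
    stop("log P contribution parameters unavailable for input ",
         paste(bad, collapse = ", "))
  }
  pr$logP
}

#' Circular-substructure fingerprints
#'
#' Extended-connectivity (circular/Morgan-type) fingerprints of the given
#' molecules as a binary matrix.
#'
#' @param smiles Character vector of SMILES.
#' @param radius Circular radius (diameter = 2 * radius; default ECFP4).
#' @return A binary matrix, one row per molecule.
#' @export
morgan_fingerprints <- function(smiles, radius = 2L) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  sdf <- ChemmineOB::convertFormat("SMI", "SDF",
                                   paste(smiles, collapse = "\n"))
  sdfset <- ChemmineR::read.SDFset(ChemmineR::read.SDFstr(
    strsplit(sdf, "\n", fixed = TRUE)[[1]]))
  fp <- ChemmineR::fingerprintOB(sdfset, paste0("ECFP", 2L * radius))
  m <- fp@fpma
  storage.mode(m) <- "integer"
  rownames(m) <- smiles
  m
}

#' Two-dimensional chemical-space map
#'
#' Embeds circular fingerprints with t-distributed stochastic neighbor
#' embedding under a fixed seed; group labels follow the reference /
#' matched-target / generated display convention.
#'
#' @param generated Character vector of generated SMILES.
#' @param reference Character vector of reference (database) SMILES.
#' @param matched Optional character vector of reference molecules matching
#'   the target properties.
#' @param seed Integer seed.
#' @param perplexity t-SNE perplexity (clamped to the feasible maximum).
#' @param radius Fingerprint radius.
#' @return A `fluogen_chemspace` tibble: `smiles`, `group`, `x`, `y`.
#' @export
chemical_space_map <- function(generated, reference, matched = character(0),
                               seed = 1L, perplexity = 30, radius = 2L) {
  all_smi <- c(reference, matched, generated)
  if (length(all_smi) < 10) stop("need at least 10 molecules to embed")
  group <- c(rep("reference", length(reference)),
             rep("matched", length(matched)),
             rep("generated", length(generated)))
  fps <- morgan_fingerprints(all_smi, radius = radius)
  perp <- min(perplexity, floor((nrow(fps) - 1) / 3))
  emb <- withr::with_seed(derive_seed(seed, "tsne"),
    Rtsne::Rtsne(fps, perplexity = perp, check_duplicates = FALSE,
                 pca = nrow(fps) > 50, partial_pca = FALSE, verbose = FALSE))
  out <- tibble::tibble(smiles = all_smi, group = group,
                        x = emb$Y[, 1], y = emb$Y[, 2])
  class(out) <- c("fluogen_chemspace", class(out))
  out
}

#' Look up generated molecules in a reference database
#'
#' Exact canonical-form matches of generated molecules against a
#' property-record table, returning each match with its stored properties
#' for target-versus-experimental comparison.
#'
#' @param generated Character vector of SMILES (any spelling) or a
#'   `fluogen_generation` tibble.
#' @param reference_db A property-record tibble keyed by canonical `smiles`.
#' @return The matching rows of `reference_db`, with a `query` column
#'   giving the generated spelling; zero rows when nothing matches.
#' @export
find_in_reference <- function(generated, reference_db) {
  if (is.data.frame(generated)) {
    generated <- generated$canonical[generated$valid]
  }
  if (length(generated) == 0) {
    return(dplyr::mutate(reference_db[0, ], query = character(0)))
  }
  can <- canonical_form(generated)
  ref_can <- canonical_form(reference_db$smiles)
  hit <- which(ref_can %in% can)
  out <- reference_db[hit, ]
  out$query <- generated[match(ref_can[hit], can)]
  out
}
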