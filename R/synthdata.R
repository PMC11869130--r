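# Synthetic stand-in for the experimental optical-property database and its
# property evaluator: a seeded random-molecule sampler, a deterministic
# surrogate oracle that reproduces the qualitative statistical structure of
# measured optical properties (absorption below emission with a
# polarity-dependent Stokes shift for charge-transfer molecules, correlated
# bandwidths, quantum yield uncorrelated with the rest), and the
# structure-based split / missing-value fill operations.

#' Solvent table
#'
#' The five solvents used throughout: water, acetonitrile (ACN),
#' dichloromethane (DCM), tetrahydrofuran (THF) and toluene, with their
#' relative permittivities and a hydrophilicity score in `[0, 1]`.
#'
#' @return A tibble with columns `solvent`, `dielectric`, `hydrophilic`.
#' @export
default_solvents <- function() {
  tibble::tibble(
    solvent = c("water", "acetonitrile", "dichloromethane",
                "tetrahydrofuran", "toluene"),
    dielectric = c(80.1, 37.5, 8.93, 7.58, 2.38),
    hydrophilic = c(1, 0.6, 0.25, 0.3, 0)
  )
}

#' Surrogate oracle parameters
#'
#' Constants of the deterministic surrogate property oracle. `lambda_base`
#' is the absorption peak of an unconjugated chromophore (nm);
#' `lambda_per_doc` the bathochromic shift per unit degree of conjugation
#' (nm/bond); `stokes_base`/`stokes_ict` control the Stokes shift, whose
#' charge-transfer term grows with solvent polarity through the reaction
#' field factor (eps - 1)/(eps + 2); `noise_scale` rescales every noise
#' standard deviation (0 gives the noiseless test mode).
#'
#' @param lambda_base,lambda_per_doc Absorption baseline and conjugation
#'   increment (nm).
#' @param stokes_base,stokes_ict Stokes-shift intercept (nm) and
#'   charge-transfer coefficient (nm per ICT unit at full polarity).
#' @param sigma_abs_base,sigma_emi_base,sigma_latent Bandwidth means and the
#'   shared molecule-level latent scale (cm-1).
#' @param logeps_base,logeps_per_atom Extinction-coefficient link.
#' @param tau_base,tau_per_phi Lifetime link (ns).
#' @param noise_lambda,noise_sigma,noise_logeps,noise_tau Noise standard
#'   deviations.
#' @param noise_scale Global noise multiplier.
#' @param seed Base seed mixed into the per-molecule noise streams.
#' @return A list of class `fluogen_oracle_params`.
#' @export
oracle_params <- function(lambda_base = 300, lambda_per_doc = 22,
                          stokes_base = 25, stokes_ict = 60,
                          sigma_abs_base = 3800, sigma_emi_base = 3200,
                          sigma_latent = 850,
                          logeps_base = 3.2, logeps_per_atom = 0.09,
                          tau_base = 1.5, tau_per_phi = 6,
                          noise_lambda = 12, noise_sigma = 150,
                          noise_logeps = 0.25, noise_tau = 0.35,
                          noise_scale = 1, seed = 20240830L) {
  stopifnot(lambda_per_doc >= 0, stokes_ict >= 0, noise_scale >= 0)
  structure(as.list(environment()), class = "fluogen_oracle_params")
}

reaction_field <- function(dielectric) (dielectric - 1) / (dielectric + 2)

#' Surrogate optical properties of a molecule in a solvent
#'
#' Deterministic given (molecule, solvent, parameters): molecule-level noise
#' is drawn from a stream seeded by the canonical form, so the same molecule
#' always receives the same values. The construction mirrors the structure
#' of measured databases: absorption shifts bathochromically with the
#' degree of conjugation; emission is absorption plus a strictly positive
#' Stokes shift whose charge-transfer term increases with solvent polarity;
#' the two bandwidths share a molecule-level latent and are therefore
#' positively correlated; the quantum yield is drawn independently of the
#' wavelengths; the lifetime is weakly linked to the quantum yield.
#'
#' @param g A valid `mol_graph` (or SMILES string).
#' @param solvent A solvent name from the solvent table, or a one-row list
#'   with `solvent`, `dielectric`.
#' @param params [oracle_params()].
#' @param solvents Solvent table.
#' @return A one-row tibble with the seven property columns.
#' @export
oracle_properties <- function(g, solvent, params = oracle_params(),
                              solvents = default_solvents()) {
  if (is.character(g)) g <- parse_structure(g)
  if (is.character(solvent)) {
    k <- match(solvent, solvents$solvent)
    if (is.na(k)) stop("unknown solvent: ", solvent)
    solv <- as.list(solvents[k, ])
  } else {
    solv <- as.list(solvent)
  }
  can <- canonical_form(g)
  doc <- degree_of_conjugation(g)$doc
  ict <- ict_strength(g)
  nconj <- length(unlist(conjugated_components(g)))

  ns <- params$noise_scale
  noise <- withr::with_seed(
    derive_seed(params$seed, "oracle", can),
    stats::rnorm(6))
  # molecule-level draws independent of solvent
  u_band <- noise[1]              # shared bandwidth latent
  z_phi <- noise[2]               # quantum-yield latent (independent)
  lam <- params$lambda_base + params$lambda_per_doc * doc +
    ns * params$noise_lambda * noise[3]
  lam <- min(max(lam, 250), 900)
  stokes <- params$stokes_base +
    params$stokes_ict * ict * reaction_field(solv$dielectric) +
    ns * 8 * abs(noise[4])
  stokes <- max(stokes, 5)
  lam_emi <- min(lam + stokes, 1000)
  if (lam_emi <= lam) lam_emi <- lam + 1
  sig_abs <- max(params$sigma_abs_base + params$sigma_latent * u_band +
                   ns * params$noise_sigma * noise[5], 500)
  sig_emi <- max(params$sigma_emi_base + 0.85 * params$sigma_latent * u_band +
                   ns * params$noise_sigma * noise[6], 500)
  log_eps <- min(max(params$logeps_base + params$logeps_per_atom * nconj +
                       ns * params$noise_logeps * noise[5] * 0.5, 2), 6)
  phi <- stats::plogis(0.9 * z_phi)
  tau <- (params$tau_base + params$tau_per_phi * phi) *
    exp(ns * params$noise_tau * noise[6] * 0.5)

  tibble::tibble(lambda_abs = lam, sigma_abs = sig_abs, log_eps = log_eps,
                 lambda_emi = lam_emi, sigma_emi = sig_emi, phi = phi,
                 tau = tau)
}

#' Build a property oracle function
#'
#' Wraps [oracle_properties()] with fixed parameters into the
#' `function(molecule, solvent)` interface expected by the evaluation
#' stack (the pluggable stand-in for a trained property predictor).
#'
#' @param params [oracle_params()].
#' @param solvents Solvent table.
#' @return A function `(g, solvent) -> one-row property tibble`.
#' @export
make_oracle <- function(params = oracle_params(),
                        solvents = default_solvents()) {
  force(params); force(solvents)
  function(g, solvent) oracle_properties(g, solvent, params, solvents)
}

# molecule sampling ------------------------------------------------------

SEED_FRAGMENTS <- list(
  aliphatic = c("CC", "CO", "CCC", "CCN"),
  mixed = c("c1ccccc1", "n1ccccc1", "c1ccsc1", "c1ccoc1", "C=C", "CC",
            "C=CC=C"),
  conjugated = c("c1ccccc1", "c1ccc2ccccc2c1", "c1ccccc1-c1ccccc1",
                 "C=Cc1ccccc1", "c1ccc(cc1)C=Cc1ccccc1", "C=CC=C",
                 "c1ccsc1-c1ccsc1")
)

#' Sample random valid molecules
#'
#' Generates molecules by seeded random legal-action walks: a walk starts
#' from a parsed seed fragment (aromatic rings, short polyenes, or aliphatic
#' chains) and repeatedly applies a random legal action, with a per-molecule
#' conjugation bias that up-weights double/triple/aromatic additions so that
#' the sample spans a wide range of conjugation lengths. A walk terminates
#' only in a valid complete state, so every returned molecule passes
#' validation and replays through the trajectory layer.
#'
#' @param n Number of molecules.
#' @param seed Integer seed; the sample is deterministic given the seed.
#' @param size_range Target heavy-atom count range (inclusive).
#' @param vocab Atom vocabulary used for the walks.
#' @return A list of `n` valid `mol_graph` objects.
#' @export
sample_molecules <- function(n, seed = 1L, size_range = c(6L, 14L),
                             vocab = default_vocabulary()) {
  stopifnot(n >= 1, length(size_range) == 2, size_range[1] >= 1)
  # neutral descriptors only: charged atoms enter via parsed fragments
  vocab <- vocab[vocab$charge == 0L, ]
  seeds_g <- lapply(SEED_FRAGMENTS, function(v) lapply(v, parse_structure))
  out <- vector("list", n)
  for (k in seq_len(n)) {
    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      g <- withr::with_seed(derive_seed(seed, "walk", k, attempt),
                            random_walk_molecule(seeds_g, size_range, vocab))
      if (!is.null(g)) break
      if (attempt > 20L) stop("molecule sampling failed repeatedly")
    }
    out[[k]] <- g
  }
  out
}

random_walk_molecule <- function(seeds_g, size_range, vocab) {
  target <- sample.int(size_range[2] - size_range[1] + 1L, 1L) +
    size_range[1] - 1L
  style <- sample(c("aliphatic", "mixed", "conjugated"), 1L,
                  prob = c(0.25, 0.4, 0.35))
  w_double <- switch(style, aliphatic = 0, mixed = 0.8, conjugated = 2.5)
  pool <- seeds_g[[style]]
  fits <- vapply(pool, n_atoms, integer(1)) <= target
  if (!any(fits)) fits <- which.min(vapply(pool, n_atoms, integer(1)))
  state <- pool[[sample(which(fits), 1L)]]
  vmax_new <- vapply(seq_len(nrow(vocab)), function(k)
    max_valence(vocab$element[k], vocab$charge[k]) -
      ifelse(is.na(vocab$h_explicit[k]), 0, vocab$h_explicit[k]), numeric(1))
  arom_ok_new <- vapply(vocab$element, function(e) ELEMENTS[[e]]$aromatic_ok,
                        logical(1))
  # valence deficit of pinned-hydrogen atoms: extra bond order each atom
  # still needs before its total valence is an allowed value
  deficit_ <- function(st) {
    occ <- occupancy(st)
    out <- numeric(n_atoms(st))
    for (i in which(!is.na(st$h_explicit))) {
      allowed <- allowed_valences(st$element[i], st$charge[i])
      a2 <- allowed[allowed >= occ[i] - 1e-9]
      out[i] <- if (length(a2) == 0) 0 else min(a2) - occ[i]
    }
    out
  }
  # growth uses single/double/triple additions only: every intermediate is a
  # completable molecule, so walks never dead-end in open aromatic systems
  # (aromatic bonds enter through the seed fragments and, downstream,
  # through model-driven generation)
  for (step in seq_len(6L * size_range[2])) {
    if (n_atoms(state) >= target) {
      # closure phase: saturate remaining pinned-valence deficits with
      # exactly-fitting carbon caps (CH3 / CH2= / CH#)
      def <- deficit_(state)
      while (any(def > 0)) {
        a <- which(def > 0)[1]
        ord <- min(def[a], 3)
        bond <- c("single", "double", "triple")[ord]
        state <- apply_action(state, action_row(
          "add", "C", 0L, as.integer(4L - ord), bond = bond,
          attach = a), strict = FALSE)
        def <- deficit_(state)
      }
      return(if (molecule_ok(state)) state else NULL)
    }
    ad <- enumerate_adds_(state, vocab, vmax_new, arom_ok_new)
    # keep the walk chemistry mundane: heteroatoms attach to carbon only,
    # multiple bonds are restricted to C=C, C=O, C=N, C#C, C#N
    new_el <- vocab$element[ad$vidx]
    att_el <- state$element[ad$attach]
    sane <- (new_el == "C" | att_el == "C") &
      (ad$bond == "single" |
         (ad$bond == "double" & new_el %in% c("C", "N", "O") &
            att_el %in% c("C", "N")) |
         (ad$bond == "triple" & new_el %in% c("C", "N") & att_el == "C"))
    leg <- which(ad$legal & sane)
    if (length(leg) == 0) {
      return(if (molecule_ok(state)) state else NULL)
    }
    bo <- ad$bond[leg]
    w <- ifelse(bo == "single", 1,
                ifelse(bo == "double", w_double, 0.08 * w_double))
    if (style == "conjugated") {
      # extend existing pi systems preferentially (polyene growth)
      multi <- state$btype %in% c("double", "triple", "aromatic")
      pi_atom <- rep(FALSE, n_atoms(state))
      pi_atom[unique(c(state$bi[multi], state$bj[multi]))] <- TRUE
      w <- w * (1 + 2.5 * (bo != "single" | pi_atom[ad$attach[leg]]))
    }
    if (all(w == 0)) w[] <- 1
    pick <- leg[sample.int(length(leg), 1L, prob = w)]
    vi <- ad$vidx[pick]
    state <- apply_action(state, action_row(
      "add", vocab$element[vi], vocab$charge[vi], vocab$h_explicit[vi],
      bond = ad$bond[pick], attach = ad$attach[pick]), strict = FALSE)
  }
  if (molecule_ok(state)) state else NULL
}

# database construction --------------------------------------------------

#' Build a synthetic optical-property database
#'
#' Samples molecules, pairs each with one or more solvents, and labels each
#' pair with the surrogate oracle. Solvent assignment is coupled to
#' lipophilicity: hydrophilic (low log P) molecules are preferentially
#' paired with water and hydrophobic ones with toluene, emulating the
#' solubility-driven composition of measured databases; this is what makes
#' solvent conditioning recoverable by the generator.
#'
#' @param n_molecules Number of distinct molecules.
#' @param seed Integer seed.
#' @param params [oracle_params()].
#' @param solvents Solvent table.
#' @param pairs_per_molecule Range of solvents drawn per molecule.
#' @param missing_rate Fraction of property cells blanked to `NA` (to
#'   exercise [fill_missing()]).
#' @param size_range Molecule size range passed to [sample_molecules()].
#' @return A tibble with columns `smiles` (canonical), `solvent`, the seven
#'   properties, `log_p`, and `filled` (comma list of filled fields, empty
#'   for observed cells).
#' @export
synth_database <- function(n_molecules = 500L, seed = 1L,
                           params = oracle_params(),
                           solvents = default_solvents(),
                           pairs_per_molecule = c(1L, 2L),
                           missing_rate = 0, size_range = c(6L, 14L)) {
  # sample until n distinct canonical structures are collected
  mols <- list(); cans <- character(0); round_ <- 0L
  while (length(mols) < n_molecules && round_ < 8L) {
    round_ <- round_ + 1L
    batch <- sample_molecules(ceiling(1.3 * n_molecules),
                              seed = derive_seed(seed, "mols", round_),
                              size_range = size_range)
    bc <- canonical_form(vapply(batch, write_structure, character(1)))
    keep <- !duplicated(bc) & !(bc %in% cans)
    mols <- c(mols, batch[keep]); cans <- c(cans, bc[keep])
  }
  if (length(mols) > n_molecules) {
    mols <- mols[seq_len(n_molecules)]; cans <- cans[seq_len(n_molecules)]
  }
  lp <- logp(cans)
  rows <- withr::with_seed(derive_seed(seed, "pairs"), {
    lapply(seq_along(mols), function(m) {
      ks <- seq.int(pairs_per_molecule[1], pairs_per_molecule[2])
      k <- ks[sample.int(length(ks), 1L)]
      # hydrophilicity coupling: hydrophilic solvents strongly prefer
      # low-log P molecules and vice versa (steep link so that solvent
      # conditioning is recoverable by the generator)
      w <- 0.02 + solvents$hydrophilic * stats::plogis(-4 * (lp[m] - 2)) +
        (1 - solvents$hydrophilic) * stats::plogis(4 * (lp[m] - 2))
      sv <- sample(solvents$solvent, k, prob = w)
      tibble::tibble(mol = m, solvent = sv)
    })
  })
  rows <- dplyr::bind_rows(rows)
  props <- dplyr::bind_rows(lapply(seq_len(nrow(rows)), function(r)
    oracle_properties(mols[[rows$mol[r]]], rows$solvent[r], params, solvents)))
  db <- dplyr::bind_cols(
    tibble::tibble(smiles = cans[rows$mol], solvent = rows$solvent),
    props,
    tibble::tibble(log_p = lp[rows$mol], filled = ""))
  if (missing_rate > 0) {
    db <- withr::with_seed(derive_seed(seed, "missing"), {
      for (p in PROPERTY_NAMES) {
        blank <- stats::runif(nrow(db)) < missing_rate
        db[[p]][blank] <- NA_real_
      }
      db
    })
  }
  db
}

#' Structure-based train/test split
#'
#' Splits records on unique canonical forms so that every solvent record of
#' a molecule lands on the same side (no structure leakage), with
#' `round((1 - ratio) * n_unique)` molecules in the test set.
#'
#' @param records A property-record tibble with a `smiles` column
#'   (canonical forms).
#' @param ratio Training fraction (default 0.9 for the 9:1 split).
#' @param seed Integer seed.
#' @return A list with `train` and `test` tibbles.
#' @export
split_by_structure <- function(records, ratio = 0.9, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1)
  uniq <- unique(records$smiles)
  if (length(uniq) < 2) stop("need at least 2 unique molecules to split")
  n_test <- round((1 - ratio) * length(uniq))
  test_mols <- withr::with_seed(derive_seed(seed, "split"),
                                sample(uniq, n_test))
  list(train = dplyr::filter(records, !(.data$smiles %in% test_mols)),
       test = dplyr::filter(records, .data$smiles %in% test_mols))
}

#' Fill missing property values with oracle predictions
#'
#' Replaces `NA` property cells by the oracle's value for that
#' molecule/solvent pair and records the provenance in the `filled` column;
#' observed values are untouched.
#'
#' @param records A property-record tibble (columns `smiles`, `solvent`,
#'   the seven properties, optionally `filled`).
#' @param oracle A `function(molecule, solvent)` as from [make_oracle()].
#' @return The completed tibble.
#' @export
fill_missing <- function(records, oracle = make_oracle()) {
  if (!"filled" %in% names(records)) records$filled <- ""
  need <- which(rowSums(is.na(records[PROPERTY_NAMES])) > 0)
  for (r in need) {
    pred <- oracle(records$smiles[r], records$solvent[r])
    miss <- PROPERTY_NAMES[is.na(unlist(records[r, PROPERTY_NAMES]))]
    for (p in miss) records[[p]][r] <- pred[[p]]
    records$filled[r] <- paste(c(
      strsplit(records$filled[r], ",")[[1]], miss), collapse = ",")
  }
  records
}

#' Read / write the property-database CSV dialect
#'
#' Columns: `smiles`, `solvent`, `lambda_abs_nm`, `sigma_abs_cm1`,
#' `log_eps`, `lambda_emi_nm`, `sigma_emi_cm1`, `phi`, `tau_ns` --
#' one row per molecule/solvent pair. This is also the reader schema for
#' externally downloaded databases.
#'
#' @param db A property-record tibble (internal column names).
#' @param path CSV file path.
#' @return `read_property_db()` returns a tibble with internal column
#'   names; `write_property_db()` returns `path` invisibly.
#' @export
write_property_db <- function(db, path) {
  out <- db
  ext <- c(lambda_abs = "lambda_abs_nm", sigma_abs = "sigma_abs_cm1",
           log_eps = "log_eps", lambda_emi = "lambda_emi_nm",
           sigma_emi = "sigma_emi_cm1", phi = "phi", tau = "tau_ns")
  names(out)[match(names(ext), names(out))] <- unname(ext)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) round(x, 6))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_property_db
#' @export
read_property_db <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  ext <- c(lambda_abs_nm = "lambda_abs", sigma_abs_cm1 = "sigma_abs",
           log_eps = "log_eps", lambda_emi_nm = "lambda_emi",
           sigma_emi_cm1 = "sigma_emi", phi = "phi", tau_ns = "tau")
  hit <- names(out) %in% names(ext)
  names(out)[hit] <- unname(ext[names(out)[hit]])
  out
}
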