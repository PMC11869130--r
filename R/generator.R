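# Sampling molecules from a trained conditional model.

#' Generate molecules for a target condition
#'
#' Builds molecules by iteratively sampling from the model's masked action
#' distribution until `terminate` is chosen or the step cap is reached,
#' starting from scratch or from a scaffold. Sampling is plain multinomial
#' over the legal-action distribution (optionally tempered), so less likely
#' actions can be selected and repeated calls yield diverse structures;
#' the whole run is deterministic given `seed`.
#'
#' @param model A fitted `fluogen_model` (or a checkpoint path).
#' @param condition The target condition (see [as_condition()]).
#' @param n_molecules Number of molecules to sample.
#' @param scaffold Optional starting scaffold: a `mol_graph` or SMILES
#'   string. Scaffold atoms and bonds are never removed; construction
#'   indices continue from the scaffold.
#' @param max_steps Cap on actions per molecule; a molecule still unfinished
#'   at the cap is marked truncated and counts as invalid.
#' @param seed Integer seed.
#' @param keep_invalid Keep invalid/truncated records in the result
#'   (default TRUE: records are returned with `valid = FALSE`).
#' @param temperature Sampling temperature.
#' @return A `fluogen_generation` tibble: one row per sampled molecule with
#'   columns `id`, `smiles`, `canonical` (NA when invalid), `valid`,
#'   `truncated`, `n_steps`, `log_prob`, and a `trace` list-column of the
#'   per-step actions with their probabilities.
#' @export
generate <- function(model, condition, n_molecules = 1L, scaffold = NULL,
                     max_steps = 120L, seed = 1L, keep_invalid = TRUE,
                     temperature = model$config$temperature) {
  stopifnot(n_molecules >= 1, max_steps >= 1)
  if (is.character(model)) model <- read_checkpoint(model)
  condition <- as_condition(condition)
  if (is.character(scaffold)) scaffold <- parse_structure(scaffold)
  if (!is.null(scaffold) && !isTRUE(validate_valence(scaffold)[1])) {
    stop("scaffold fails valence validation")
  }
  scaffold_n <- if (is.null(scaffold)) 0L else n_bonds(scaffold)

  one <- function(k) {
    state <- if (is.null(scaffold)) mol_graph() else scaffold
    steps <- list(); probs <- numeric(0)
    truncated <- TRUE
    for (s in seq_len(max_steps)) {
      dist <- action_distribution(state, condition, model,
                                  temperature = temperature)
      leg <- which(dist$legal)
      pick <- leg[sample.int(length(leg), 1L, prob = dist$prob[leg])]
      act <- dist[pick, ]
      probs <- c(probs, act$prob)
      steps[[length(steps) + 1L]] <- act
      if (act$kind == "terminate") { truncated <- FALSE; break }
      state <- apply_action(state, act)
    }
    valid <- !truncated && molecule_ok(state)
    trace <- dplyr::bind_rows(steps)
    smi <- if (n_atoms(state) > 0) write_structure(state) else NA_character_
    tibble::tibble(
      id = k, smiles = smi,
      canonical = NA_character_, valid = valid, truncated = truncated,
      n_steps = length(probs), log_prob = sum(log(probs)),
      trace = list(trace))
  }

  out <- withr::with_seed(derive_seed(seed, "generate"),
                          dplyr::bind_rows(lapply(seq_len(n_molecules), one)))
  if (any(out$valid)) {
    out$canonical[out$valid] <- canonical_safe(out$smiles[out$valid])
  }
  if (!keep_invalid) out <- dplyr::filter(out, .data$valid)
  attr(out, "condition") <- condition
  attr(out, "scaffold_bonds") <- scaffold_n
  class(out) <- c("fluogen_generation", class(out))
  out
}

#' Recompute the likelihood of a stored generation trace
#'
#' Replays a trace action by action under a (possibly reloaded) model and
#' returns the recomputed per-step probabilities; used to audit that stored
#' traces match the checkpointed model.
#'
#' @param trace The `trace` tibble of one generation record.
#' @param condition The condition it was generated under.
#' @param model A `fluogen_model`.
#' @param scaffold Optional scaffold the generation started from.
#' @return Numeric vector of per-step chosen-action probabilities.
#' @export
trace_likelihood <- function(trace, condition, model, scaffold = NULL) {
  if (is.character(scaffold)) scaffold <- parse_structure(scaffold)
  state <- if (is.null(scaffold)) mol_graph() else scaffold
  out <- numeric(nrow(trace))
  for (k in seq_len(nrow(trace))) {
    dist <- action_distribution(state, condition, model)
    y <- match_action(dist, trace[k, ])
    out[k] <- if (is.na(y)) 0 else dist$prob[y]
    if (trace$kind[k] != "terminate") state <- apply_action(state, trace[k, ])
  }
  out
}
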