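# Small functional-group pattern table: electron-donating and
# electron-withdrawing groups used (a) as intramolecular-charge-transfer
# proxies by the surrogate property oracle and (b) as structural features by
# the conditional action model. These are deliberately coarse graph
# patterns, not a claim about photophysics.

#' Count donor / acceptor groups
#'
#' Donors: sp3-type nitrogens and oxygens (amino, hydroxy, alkoxy) carrying
#' only single bonds and no formal charge, outside aromatic rings.
#' Acceptors: nitro groups (`[N+](=O)[O-]`), cyano groups (`C#N`) and
#' carbonyls (`C=O`).
#'
#' @param g A `mol_graph`.
#' @return Integer count.
#' @export
count_donor_groups <- function(g) {
  if (n_atoms(g) == 0) return(0L)
  multi <- g$btype %in% c("double", "triple", "aromatic")
  has_multi <- rep(FALSE, n_atoms(g))
  has_multi[unique(c(g$bi[multi], g$bj[multi]))] <- TRUE
  sum((g$element %in% c("N", "O")) & g$charge == 0 & !g$aromatic & !has_multi)
}

#' @rdname count_donor_groups
#' @export
count_acceptor_groups <- function(g) {
  if (n_bonds(g) == 0) return(0L)
  n_acc <- 0L
  # nitro: N(+1) with a double bond to O and a single bond to O(-1)
  for (i in which(g$element == "N" & g$charge == 1L)) {
    nb_d <- c(g$bj[g$bi == i & g$btype == "double"],
              g$bi[g$bj == i & g$btype == "double"])
    nb_s <- c(g$bj[g$bi == i & g$btype == "single"],
              g$bi[g$bj == i & g$btype == "single"])
    if (any(g$element[nb_d] == "O" & g$charge[nb_d] == 0L) &&
        any(g$element[nb_s] == "O" & g$charge[nb_s] == -1L)) {
      n_acc <- n_acc + 1L
    }
  }
  # cyano: C#N
  tri <- which(g$btype == "triple")
  n_acc <- n_acc + sum(
    (g$element[g$bi[tri]] == "C" & g$element[g$bj[tri]] == "N") |
    (g$element[g$bi[tri]] == "N" & g$element[g$bj[tri]] == "C"))
  # carbonyl: C=O with neutral O (nitro oxygens are on N, not double-counted)
  dbl <- which(g$btype == "double")
  n_acc <- n_acc + sum(
    ((g$element[g$bi[dbl]] == "C" & g$element[g$bj[dbl]] == "O" &
        g$charge[g$bj[dbl]] == 0L) |
     (g$element[g$bi[dbl]] == "O" & g$element[g$bj[dbl]] == "C" &
        g$charge[g$bi[dbl]] == 0L)))
  as.integer(n_acc)
}

#' Intramolecular charge-transfer strength proxy
#'
#' Operationalized as `min(donors, acceptors)` capped at `cap`: a molecule
#' needs at least one donor--acceptor pair for charge-transfer character,
#' and additional pairs strengthen it with saturation.
#'
#' @param g A `mol_graph`.
#' @param cap Saturation cap (default 3).
#' @return Integer in `0..cap`.
#' @export
ict_strength <- function(g, cap = 3L) {
  min(count_donor_groups(g), count_acceptor_groups(g), cap)
}
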