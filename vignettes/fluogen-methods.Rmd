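---
title: "Conditional autoregressive design of fluorophores: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional autoregressive design of fluorophores: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The design problem

Chromophore and fluorophore development asks for molecules whose optical
behaviour in a chosen solvent matches a specification: absorption and
emission peak positions (`lambda_abs`, `lambda_emi`, nm), the corresponding
bandwidths (`sigma_abs`, `sigma_emi`, cm^-1^), the molar extinction
coefficient (as `log_eps`), the photoluminescence quantum yield (`phi`) and
lifetime (`tau`, ns). fluogen implements a generative route to this goal:
molecules are built atom by atom by a model conditioned on the seven target
properties plus the solvent, so that sampling the model proposes candidate
structures biased toward the target.

## Molecular graphs and the action formalism

A molecule is a heavy-atom graph. Each atom carries an element symbol (the
common organic set C, N, O, S, F, Cl, Br, I, P, Si, B), a formal charge in
-2..+2, and a hydrogen count; hydrogens are never graph nodes. Bonds take
one of four types -- single, double, triple, aromatic -- and aromatic bonds
contribute 1.5 to bond-order sums.

Generation proceeds by three actions: **add** a new atom to an existing
atom with a chosen bond, **connect** two existing atoms (ring closure), or
**terminate**. The legal-action set of a partial molecule is enumerated
explicitly: an addition or connection is legal when both touched atoms
retain the valence capacity for the new bond. Three refinements make the
1.5-per-aromatic-bond accounting workable during construction:

* ring-fusion atoms (three aromatic bonds, nominal occupancy 4.5) receive
  0.5 occupancy slack, because their Kekulé reality is 4;
* pi lone-pair **donor** atoms (pyrrole-type N--H, furan O, thiophene S,
  borole B) receive slack 0.5 per aromatic bond, because all their aromatic
  bonds kekulize to single bonds. During construction the donor
  classification is permissive (a nitrogen that *could* complete as a donor
  is treated as one); the exact check happens at termination;
* aromatic and localized multiple bonds never mix on one atom. Quinoid
  motifs must be written kekulized; this keeps intermediate states
  completable and canonicalizable.

A completed molecule must be connected, have every aromatic bond inside a
ring (aromatic degree 2--3 per atom), admit an alternating Kekulé
assignment (found by backtracking on the aromatic subgraph), and give every
atom an allowed total valence. Electron counting (Hückel's rule) is *not*
checked: kekulizability is the acceptance rule, which follows mainstream
sanitizer behaviour for the common ring systems but accepts some exotic
rings (e.g. small all-carbon "aromatic" cycles) that stricter perception
would reject.

**Termination legality.** Terminate is legal exactly when the current state
is a complete valid molecule. A small number of constructed states are dead
ends (no action can complete them); in those states terminate becomes legal
as an escape so that the action distribution is always defined, and the
escaped molecule simply fails validation and is counted invalid. This
choice keeps the invariant "every reachable state has at least one legal
action" without hiding invalid generations.

SMILES parsing and writing are implemented directly on this graph model so
that the aromatic bond type of the action vocabulary is preserved
round-trip; canonical ordering, the Crippen-type atom-contribution log P,
and extended-connectivity (circular) fingerprints are delegated to
OpenBabel through ChemmineOB/ChemmineR, and the 2-D chemical-space
embedding to Rtsne. The canonical SMILES string is the database key
throughout.

## Trajectory decomposition

Training data are action sequences. A molecule is decomposed by a seeded
stochastic depth-first search: the start atom is uniform over heavy atoms,
neighbor visit order is a uniform shuffle, tree edges become additions, and
ring closures are emitted as connections when the search revisits an
existing atom (several closures at one atom are emitted in atom-index
order). Each atom's add action pins its *total* hydrogen count, so a
finished molecule is exactly saturated and "fully built" is a property the
model can read off the state. Every decomposition replays to a graph with
the same canonical form; different seeds give different but equivalent
trajectories, which training uses as data augmentation (one fresh
decomposition per molecule per epoch).

## The conditional action model

The model scores each legal action `a` of a state `s` under condition `c`
bilinearly,

    score(s, a | c) = phi(s, a)' W psi(c),

and normalizes with a masked softmax (illegal actions have exactly zero
probability). `psi(c)` is the encoded condition: the seven properties
z-scored with training statistics, a solvent indicator over the known
solvent table (whose weight columns act as a learned per-solvent
embedding), and the z-scored dielectric constant, which also serves as the
fallback representation for solvents outside the table.

`phi(s, a)` collects structural features of the action in its state:
action-kind indicators; the added atom's vocabulary identity; bond type and
order; whether the addition extends a conjugated system; attachment-site
element, aromaticity, degree, occupancy and construction-order position;
ring size for connections; and, on the terminate action, global state
descriptors (size, ring count, conjugated-bond count, donor/acceptor group
counts, heteroatom fractions). Because within-state softmax competition
cancels any feature shared by all candidates, the map also includes
conjunction features -- atom-type x attachment-occupancy, bond-type x
attachment-occupancy and atom-type x attachment-position -- without which a
linear scorer provably cannot prefer different additions in different
construction contexts. All features are graph invariants or
construction-order quantities, so the teacher-forcing loss is invariant
under relabeling of the training molecule; this is the package's
permutation-equivariance contract, met here by a feature-based scorer
rather than a trainable message-passing network (a deliberate design
choice: the bilinear model trains in minutes on one CPU at the package's
study scale, fits a single trajectory to certainty, and leaves the encoder
behind the same interface should a richer one be substituted).

Training minimizes the mean negative log-probability of recorded actions
with Adam (default rate 0.08, batches of 16 molecules, 3--4 epochs), one
fresh stochastic decomposition per molecule per epoch. All randomness
derives from one integer seed via keyed hashing, so a (database, config,
seed) triple reproduces its loss trace bit for bit. Checkpoints are JSON
with weights printed at full IEEE precision (`%.17g`), so save/load
round-trips are bit-identical.

## Generation

Sampling starts from scratch or a scaffold (whose atoms and bonds are never
removed; construction indices continue from it) and draws actions
multinomially from the masked distribution -- deliberately not greedy, so
less likely actions keep the output diverse -- until terminate or a step cap
(default 120 actions; capped molecules count invalid). Each record stores
the action trace with per-step probabilities; the product of stored
probabilities is auditable against a recomputation under the reloaded
checkpoint.

## The surrogate property oracle and synthetic database

Paper-scale training data (tens of thousands of measured molecule/solvent
pairs) and a trained property predictor are outside desk scale, so the
package ships a synthetic stand-in with the qualitative statistical
structure of measured optical databases:

* absorption shifts bathochromically with the **degree of conjugation**
  (DOC: bond count between the farthest atoms of the conjugated backbone),
  `lambda_abs = 300 + 22 * DOC + noise` nm, clamped to [250, 900];
* emission is absorption plus a strictly positive Stokes shift whose
  charge-transfer term grows with solvent polarity through the reaction
  field factor `(eps - 1)/(eps + 2)`:
  `stokes = 25 + 60 * ICT * f(eps) + noise` nm. ICT strength is
  operationalized as `min(donors, acceptors)` capped at 3, counting
  amino/alkoxy-type donors and nitro/cyano/carbonyl acceptors -- a toy
  proxy chosen so solvent effects are recoverable, not a photophysical
  claim. With it, a strong charge-transfer dye shows a Stokes shift of
  roughly 80 nm in toluene versus about 190 nm in acetonitrile, matching
  the magnitude of solvatochromic shifts in real dye data;
* the two bandwidths share a molecule-level latent (hence correlate at
  about 0.95); `log_eps` grows with conjugated-atom count; the quantum
  yield is drawn independently of everything else (measured quantum yields
  correlate poorly with other optical properties), and the lifetime is
  weakly tied to it.

Per-molecule noise streams are seeded from the canonical form, so the
oracle is a deterministic function of (molecule, solvent, parameters);
`noise_scale = 0` gives the exact noiseless links used by unit tests.
Strict Stokes positivity for every record is enforced -- stricter than
reality, where rare negative shifts occur.

The molecule sampler builds valid structures by seeded random legal-action
walks from seed fragments (aromatic rings and ring assemblies, short
polyenes, aliphatic chains) with a per-molecule conjugation style, growth
restricted to mundane chemistry (heteroatoms attach to carbon; multiple
bonds only C=C, C=O, C=N, C#C, C#N), and a closure phase that caps
remaining valence deficits so every walk ends in a valid molecule. The
resulting samples span DOC 0 to about 15. Database construction couples
solvent assignment to lipophilicity -- hydrophilic (low log P) molecules
are preferentially paired with water, hydrophobic ones with toluene --
emulating the solubility-driven composition of measured databases; this
coupling is what makes solvent conditioning learnable. What the synthetic
data do *not* emulate: real structural diversity (walks explore a narrow
grammar), measurement error structure, tautomers and stereochemistry, and
any genuine photophysics; passing tests therefore demonstrate that the
pipeline recovers the planted structure, not that it predicts real dyes.

## Evaluation stack

* **Validity** = valid / generated (valence-valid and connected);
  **uniqueness** = distinct canonical forms / valid; **novelty** = distinct
  canonical forms not in the training set / distinct canonical forms. The
  conventions are printed in every report; with them the three fractions
  are ordered the way published generative-chemistry numbers are.
* **Fraction within target** counts a molecule if and only if all seven
  oracle-scored properties lie inside `target +/- window` simultaneously
  (the joint reading of "within the predictor's error range"; per-property
  rates are reported as diagnostics). The default windows
  (lambda +/- 25 nm, sigma +/- 700 cm^-1, log eps +/- 0.35, phi +/- 0.12,
  tau +/- 50 % relative) are configuration standing in for a property
  predictor's error ranges, not measured values.
* **Stokes shift** is `lambda_emi - lambda_abs`; negative values are
  flagged, not dropped.
* **DOC** is computed per conjugated component (double/triple/aromatic
  bonds plus single bonds bridging two pi atoms) by all-pairs shortest
  paths restricted to the component, maximized over components, ties broken
  by the lowest atom-index pair.
* **Chemical-space maps** embed ECFP4-type circular fingerprints with
  t-SNE under a fixed seed, with reference / matched-target / generated
  group labels; **reference lookup** joins generated molecules to a
  property table on canonical form.

## Study sizes and numerical choices

The shipped experiments use a 2,000-molecule synthetic database (one
solvent pair per molecule, sizes 6--16 heavy atoms), 4 training epochs, 300
generations per emission target and 150 per solvent condition; these sizes
make the full conditional-recovery study complete in minutes on one CPU
while leaving the ordering effects (emission target -> oracle emission and
DOC; polar solvent -> Stokes shift; water -> log P) statistically obvious.

One design point deserves emphasis: the solvent-effect comparison cannot
use identical wavelength targets in both solvents, because a
well-calibrated conditional generator then delivers the conditioned Stokes
gap in *each* evaluation solvent and the polar/apolar means equalize by
construction -- the better the model, the smaller the contrast. The
comparison therefore conditions on a large-Stokes charge-transfer target
(emission 90 nm above absorption, the in-vivo-imaging design regime),
which is reachable in acetonitrile but exceeds the surrogate oracle's
charge-transfer ceiling in toluene; the solvent physics then remains
identifiable regardless of model calibration.
Softmax scores are max-shifted before exponentiation; probability sums are
asserted to 1e-9; valence capacity comparisons carry a 1e-9 tolerance;
decimal weights are serialized at 17 significant digits. Degenerate inputs
are defined explicitly: the empty state admits only first-atom additions;
single atoms are connected; molecules without pi bonds have DOC 0.

## Known limitations

The SMILES layer covers the organic subset, brackets with charge and
hydrogen counts, rings and branches; stereo markers are accepted and
discarded, isotopes ignored, multi-fragment input rejected. Aromatic
perception is by kekulizability, not electron counting. The bilinear scorer
has no message passing, so structural context enters only through the
hand-specified features; conditioning effects subtler than the planted
monotone links may be beyond it. The surrogate oracle is a planted-structure
device; none of its constants are fitted to measurements.
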