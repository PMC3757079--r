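---
title: "Characterizing disordered peptide ensembles with idpens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing disordered peptide ensembles with idpens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpens)
```

## The problem

An intrinsically disordered peptide such as IAPP (amylin) does not fold into
a single structure; it populates an ensemble of interconverting conformers.
The biologically meaningful description is therefore statistical: the folds
present, their abundances, their per-residue secondary structure and
flexibility, and their relative solvation energies. `idpens` implements this
characterization for 37-residue IAPP-like peptides and pairs it with a
synthetic-ensemble generator so that every analysis stage can be tested
against known ground truth. This vignette records the models, the tunable
parameters, the numerical choices, and the limits of what the synthetic
tests demonstrate.

## The synthetic generator

The generator is a first-class module, not a test fixture. It emulates the
three folds reported for IAPP monomer ensembles, at their canonical residue
ranges:

* **helix-coil** — coil 1–7, helix 8–17, coil 18–37;
* **helix-hairpin** — helix 8–17 plus a short C-terminal hairpin with
  strands 25–27 and 33–36 and loop 28–31;
* **β-hairpin** — strands 9–17 and 23–33 with turn 18–22.

Backbones are built residue-by-residue from internal coordinates (the NeRF
construction) with standard geometry (N–CA 1.458 Å, CA–C 1.525 Å, C–N
1.329 Å, C=O 1.231 Å; angles N–CA–C 111.2°, CA–C–N 116.6°, C–N–CA 121.9°;
ω = 180°). Helix segments use (φ, ψ) = (−57°, −47°) and strand segments
(−139°, 135°) — standard ideal values chosen so that the hydrogen-bond
patterns of each fold emerge from geometry alone; turn and coil residues
take entries from small bundled dihedral tables, assigned cyclically by
residue index so that generation is deterministic. The chain builder places
the amide H in the C(i−1)–N–CA plane opposite the bond bisector and a
C-beta by the standard tetrahedral improper (−122° for L-amino acids,
verified against an idealized residue template).

**Hairpin closure.** Ideal dihedrals do not register cross-strand hydrogen
bonds, so each hairpin motif carries an intended bond list (innermost pair
first, e.g. O17↔H23 outwards for the β-hairpin) and a set of free
dihedrals (the turn plus one flanking residue per strand). Closure is by
coordinate descent over those φ/ψ: the objective combines the O···H
distance deviation from 1.95 Å (long-range guidance), the Kabsch–Sander
bond energy driven towards −2.5 kcal/mol (penalizing over-deep one-sided
bonds, which otherwise trap the descent in sheared registries), and a
quadratic steric penalty on backbone heavy atoms closer than 2.2 Å (ideal
helices and sheets stay above 3 Å, so the penalty is inactive in correct
geometry). The search zips the hairpin from the turn outwards (innermost
bond pair first), retries from fixed turn-table initializations, applies
deterministic (seedless) basin-hopping perturbations, adds crankshaft
moves (ψ\_i up, φ\_{i+1} down — a near-rigid rotation of the downstream
segment), and falls back to a Nelder–Mead polish whose concerted simplex
moves resolve the shear that one-dihedral-at-a-time descent cannot. A
conformer converges when every intended bond scores below −0.5 kcal/mol
and no backbone heavy-atom contact is under 1.7 Å; non-converged conformers
are flagged so callers may discard them.

**Prolines and registry shifts.** A proline has no amide H and cannot
donate. When a sequence's prolines block bonds of the canonical registry
(e.g. rat IAPP with P25/P28/P29), the generator searches alternatives: the
canonical ladder minus the blocked bonds plus one further rung (e.g.
recruiting the 23↔37 pair), and antiparallel registries shifted by one or
two residues whose donors are all proline-free (for the rat helix-hairpin
this selects pairs 26↔35 and 24↔37). This mirrors the registry adjustment
real proline-containing hairpins adopt. The registry is chosen once per
motif and pinned for all conformers of an ensemble.

**Sampling.** Each conformer draws a mixture component (seeded), jitters
every dihedral of the motif's pre-closed canonical backbone by
Normal(0, σ), rebuilds, and re-refines closure from the warm start. If a
built conformer contains any atom pair closer than 0.5 Å the jitter is
redrawn (continuing the seeded stream, at most 20 attempts, keeping the
least-clashing attempt), so ensembles satisfy the validity invariants.
Identical spec and seed give bit-identical ensembles, and the caller's RNG
state is restored. The variant presets carry the reported per-variant fold
abundances (pig/rat 0.87/0.13; cat 0.28/0.25/0.47; human 0.15/0.09/0.75)
and a default jitter of σ = 3°, at which classification of generated
conformers is essentially error-free while the clusters remain structurally
diverse — a level we consider realistic for distinguishable sub-states of a
disordered ensemble.

**What the generator does not emulate.** There is no energy function, no
Boltzmann weighting, no kinetics, no side chains beyond C-beta, and no
conformational exchange between folds within a "trajectory"; blocks are
i.i.d. draws, so block statistics test the estimator arithmetic, not true
convergence behaviour. Passing tests therefore demonstrate that the
analysis stages recover known composition, geometry and closed forms — not
that they would reproduce any particular simulation's absolute values.

## Secondary structure

The assigner is DSSP-style rather than a re-implementation of STRIDE (whose
knowledge-based torsional potentials are not fully specified in the
literature): Kabsch–Sander energies
`E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` define bonds
below −0.5 kcal/mol; α-helix (H) needs two consecutive i→i+4 turns, 3₁₀
(G) two i→i+3 turns, strands (E) come from ladders of ≥ 2 β-bridges
(isolated bridges are B), turns (T) bracket an i→i+3/4/5 bond, else coil
(C). Priority is H > G > E > B > T. Residue 1 and prolines never donate.
Aggregation for reporting is helix = {H, G}, sheet = {E, B}, turn = {T},
coil = {C}; because turn and coil are often discussed jointly for IDPs, a
merged 3-class profile is available (`merge_turn_coil = TRUE`). A dihedral
mode (boxes of ±40° around the canonical helix/strand values, then the
turn-table regions) exists mainly to ground-truth the generator; dihedral
comparisons are rounded to 10⁻⁶ degrees so assignment is exactly invariant
under rigid motion.

## Clustering and super-families

Pairwise Cα-RMSD uses per-pair optimal superposition (Kabsch, SVD with
reflection correction), not a shared reference frame. Families come from
the greedy neighbor-count algorithm at a 3.0 Å cutoff: count neighbors
among unassigned structures, remove the most-connected structure (the
centroid) with its neighbors, repeat. Two choices the original protocol
leaves open are fixed here for determinism: neighbor counts are recomputed
after each removal, and ties break to the lowest structure index.

The super-family merge rule splits the chain at residue 17/18. More helix
than sheet in the N-part makes a conformer helix-rich (a tie fails the
test and classifies as β-hairpin); a helix-rich conformer is a
helix-hairpin only with strictly more than four sheet residues in the
C-part — four residues being exactly the minimal 2:2 hairpin, the boundary
case maps to helix-coil and is unit-tested. Classification can inherit the
family centroid's label (default, matching the merge-of-families reading)
or use each frame's own string; on synthetic data at σ ≤ 3° both
granularities agree with ground truth at ≥ 95%.

## Flexibility and solvation

RMSF superposes every conformer onto the subset's first conformer over the
Cα of residues 1–17 (the fold's rigid part; the range is a parameter), then
takes per-residue root-mean-square deviations about the mean structure.
Using the first conformer rather than an iterated mean reference keeps the
estimator simple; at the ensemble sizes used the difference is well inside
the sampling noise. Profiles are computed separately per super-family.

Solvation scores each conformer with an OBC-style generalized Born model:
HCT pairwise-descreening integrals, tanh rescaling with (α, β, γ) =
(1.0, 0.8, 4.85), intrinsic-radius offset 0.09 Å, solvent dielectric 78.5,
and Debye screening κ = 0.316·√M Å⁻¹ (0.1413 at the default 0.2 M, 298 K);
the energy sums over ordered pairs with
`f_ij = sqrt(r² + R_i R_j exp(−r²/(4 R_i R_j)))` and `f_ii = R_i`. The
surface term is γ·SASA with γ = 0.005 kcal/(mol·Å²), areas by Shrake–Rupley
sampling on a deterministic Fibonacci lattice (960 points; coordinates are
first rotated into a principal-axes frame with skewness-fixed signs so the
result is rigid-motion invariant to machine precision). The bundled per-atom
parameter table (backbone + C-beta charges summing to zero per residue,
Bondi-derived radii, standard OBC scales) is a fixture: formal side-chain
and terminal charges are added from an explicit protonation convention, and
only orderings, limits and relative values — fold-to-fold and
variant-to-variant differences, as in the reported solvation tables — are
meaningful, never absolute energies of any particular force field.

## Other numerical choices

* Residue indexing is 1-based everywhere.
* Amide hydrogens absent from an input PDB are reconstructed on read
  (1.01 Å from N, anti to the C(i−1)-N-CA bisector); files that provide H
  keep their own.
* The published per-variant formal charges cannot be reproduced by any one
  protonation rule, so `formal_charge()` takes the convention as an
  explicit parameter (default: K/R +1, H 0, D/E −1, N-terminus +1, amidated
  C-terminus 0).
* Cat and pig preset sequences are synthetic stand-ins constructed from the
  human sequence and the substitutions that distinguish those variants;
  human and rat are the standard published sequences. Backbone-level
  analyses depend on the sequence only through proline positions and
  charged side chains.
* Block partitions put the remainder in the earlier blocks; block
  statistics use the sample standard deviation (divisor k−1) over the last
  k = 3 of 6 blocks. "Exponentially spaced" replica temperatures are read
  as a geometric progression with exact endpoints.
* Report sizes: the bundled analyses and tests run at n = 150–2000
  conformers, sizes at which preset mixture weights are recovered within
  binomial error and the pipeline stays interactive on a single core.

## Known limitations

Synthetic ensembles are i.i.d. mixtures, so abundances converge faster than
in a correlated trajectory; the hairpin-closure refinement is a geometric
device, not an energy minimization; solvation energies are comparative
only; and the proline registry search covers shifts of up to two residues,
which suffices for the bundled sequences but is not a general β-sheet
registry predictor.
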