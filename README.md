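# idpens

Conformational-ensemble analysis for intrinsically disordered peptides,
built around the 37-residue islet amyloid polypeptide (IAPP, amylin).

IAPP is a calcitonin-family hormone that is cosecreted with insulin. In some
species (human, cat) the peptide aggregates into amyloid fibrils — a process
linked to type 2 diabetes — while in others (rat, pig) it does not. Because
the monomer is intrinsically disordered, its "structure" is an ensemble of
interconverting conformers, and the questions that matter are statistical:
which folds does the ensemble populate, in what proportions, how flexible and
how soluble is each fold? `idpens` implements that characterization as a
reusable, tested pipeline, together with a seeded generator of synthetic
backbone ensembles on which every stage can be validated against ground
truth.

## What the package computes

Given an ensemble of conformers (read from a multi-model PDB file or built
by the generator):

* **Secondary structure** per residue, from backbone coordinates. Hydrogen
  bonds are scored with the Kabsch–Sander electrostatic model,
  `E = 0.084 · 332 · (1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` kcal/mol, a bond
  being declared below −0.5 kcal/mol; DSSP-style patterns then assign
  H/G/E/B/T/C codes, aggregated to helix / sheet / turn / coil propensities
  (a dihedral-proximity mode is available for ground-truthing).
* **Structural families**, by greedy neighbor-count clustering: pairwise
  Cα-RMSD after optimal (Kabsch) superposition, a 3.0 Å cutoff, and repeated
  removal of the structure with the most neighbors together with its
  neighbors, until all conformers are assigned.
* **Super-families**, by a two-part rule on the secondary structure: a
  conformer is *helix-rich* if residues 1–17 contain more helix than sheet
  (otherwise it is a **β-hairpin**); a helix-rich conformer with more than
  four sheet residues in 18–37 is a **helix-hairpin**, else a **helix-coil**.
  Abundances are reported as mean ± sample standard deviation over the last
  three of six trajectory-style blocks.
* **Flexibility**: per-residue Cα RMSF after superposition of the rigid
  N-terminal part (residues 1–17), computed separately per super-family.
* **Solubility**: a generalized Born (OBC-style effective radii, 0.2 M
  Debye screening) electrostatic solvation energy plus a Shrake–Rupley
  surface-area term at γ = 0.005 kcal/(mol·Å²), reported per super-family
  relative to the helix-coil fold and across variants relative to a
  reference variant.
* **Utilities**: equal-block partitions for convergence statistics and the
  geometric replica-exchange temperature ladder
  `T_i = T_min (T_max/T_min)^{i/(n−1)}` (defaults 270–465 K, 16 replicas).

The synthetic generator builds 37-residue backbones from internal
coordinates (NeRF), realizes the three folds at their canonical residue
ranges (helix 8–17; C-terminal hairpin strands 25–27/33–36 with loop 28–31;
β-hairpin strands 9–17/23–33 with turn 18–22), closes hairpins by
coordinate descent on the loop dihedrals against the intended cross-strand
hydrogen bonds, applies seeded Normal(0, σ) dihedral jitter, and records
per-conformer ground-truth labels.

## Worked example

```r
library(idpens)

res <- run_pipeline(run_config(input = "rat", n = 200, sigma = 3, seed = 42,
                               solvation = FALSE))
res$abundance
#>           label abundance  std count centroid
#> 1    helix-coil     0.899 0.07   174       96
#> 2 helix-hairpin     0.101 0.07    26       16
res$profile
#> SSProfile over 200 conformers (mode: hbond )
#> ensemble class fractions:
#> helix sheet  turn  coil
#> 0.270 0.021 0.006 0.702
length(res$clusters$families)
#> [1] 7
```

The rat preset emulates a non-amyloidogenic ensemble: two super-families,
dominated by the helix-coil fold (~0.90 recovered here against a generator
weight of 0.87, with the block standard deviation quantifying the sampling
uncertainty), and low overall sheet content. The `human` preset adds the
β-hairpin fold and yields three super-families. With `solvation = TRUE` the
result also carries a per-super-family GB+SASA table, and `out_dir` writes
all report tables (TSV), centroid structures (PDB) and a JSON run manifest;
identical config and seed give byte-identical outputs.

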