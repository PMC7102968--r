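---
title: "Characterizing protein-nucleic-acid complexes: methods and design choices"
author: "aptcomplex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing protein-nucleic-acid complexes: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptcomplex)
```

## Scope

`aptcomplex` characterizes complexes between a homodimeric
nucleic-acid-binding protein (the motivating system is the tetracycline
repressor TetR, whose dimer reads operator DNA with two N-terminal
DNA-binding heads) and a bound nucleic acid, either double-stranded
operator DNA or a monomeric RNA ligand such as a SELEX-derived aptamer.
The package answers five questions about such a complex:

1. **Conformation**: which inter-domain arrangement does the protein
   adopt, measured by a domain-anchored superposition protocol?
2. **Interface**: which residues touch the nucleic acid, how much
   surface is buried, and through which interaction types?
3. **Ligand fold**: what are the backbone torsions, glycosidic classes,
   base pairs (with Leontis-Westhof edge/orientation labels), stacking
   runs and flipped-out bases of the RNA?
4. **Symmetry**: does the dimer's two-fold axis extend to the ligand?
5. **Energetics**: what do calorimetric and mobility-shift titrations
   say about affinity, enthalpy and entropy of binding?

## Superposition and the anchored-domain protocol

`kabsch_superpose()` computes the least-squares proper rotation via the
SVD of the cross-covariance matrix, with the determinant correction
that excludes reflections. Degenerate (collinear) point sets are
rejected rather than silently resolved.

Inter-domain rearrangements are measured with
`anchored_domain_rmsd()`: Cα atoms of a conformationally invariant
anchor domain, pooled over both protomers, define the transform; the
probe domain r.m.s.d. is then evaluated under that transform **without
refitting**. This separates "how well do the rigid cores agree" from
"how differently are the reading heads oriented". The default anchor is
the effector-binding-domain segment set 48-66, 73-103, 108-129,
131-137, 139-151, 166-173, 179-180, 183-202 (`ebd_domain()`); the
probe defaults to residues 2-47 per protomer (`nbd_domain()`), i.e.
everything N-terminal of the first anchor segment, which covers the
three-helix DNA-reading head. The probe window is configurable because
domain boundaries are a modeling choice, not an observable.

Two conventions matter and are applied automatically:

* **Chain pairing.** Crystallographic chain labels are arbitrary, so
  both protomer correspondences (A-A/B-B and A-B/B-A) are tried and the
  one minimizing the anchor r.m.s.d. is kept and reported.
* **Gap handling.** A residue pair enters the fit only when the Cα is
  modeled in both structures; pair counts are always reported so a
  reader can tell a 356-pair fit from a 100-pair one.

`inter_residue_distance()` reports marker-residue displacements under
the anchor transform, averaged over the two protomer copies, because
each marker occurs twice in a dimer.

## Interface census and buried areas

`find_contact_residues()` counts a protein residue as a contact residue
if **any** of its heavy atoms lies within the cutoff (default 3.7
Angstroms) of **any** nucleic-acid atom. The census is validated
against a brute-force all-pairs oracle in the test suite.

Solvent-accessible surface areas use a Shrake-Rupley construction
(`solvent_accessible_area()`): each atom's sphere (van der Waals radius
from the Bondi single-source table, plus a 1.4-Angstrom water probe)
is sampled on a deterministic golden-section spiral lattice of 960
points, and a point is accessible if it falls inside no neighboring
expanded sphere. The lattice is deterministic, so areas are exactly
reproducible; doubling the point count moves any area by less than 1%.
The buried area of a protein domain is
`SASA(protein alone) - SASA(complex)` restricted to the domain's
atoms (`buried_area_decomposition()`). Because published interface
areas rarely state their algorithm, radius set or point density,
agreement with literature values should be judged at the ±10% level.

Typed interactions are gated permissively and report their geometry so
users can re-gate:

| interaction | gate | default |
|---|---|---|
| hydrogen bond | donor-acceptor distance | ≤ 3.5 Å |
| hydrogen bond | antecedent-donor-acceptor angle | ≥ 90° |
| π-π stacking | ring-centroid distance | ≤ 4.5 Å |
| π-π stacking | interplanar angle | ≤ 30° |
| cation-π | cation-centroid to ring-centroid | ≤ 6.0 Å |
| cation-π | off-normal angle | ≤ 45° |

The hydrogen-bond criteria are heavy-atom criteria: deposited crystal
structures at moderate resolution carry no hydrogens, so donors and
acceptors come from a fixed chemistry table (N/O donors with their
covalent antecedents, N/O acceptors, for the 20 amino acids and the
standard nucleotides) and the angle gate uses the donor's antecedent
where modeled. Bidentate interactions (e.g. an arginine guanidinium
donating two bonds to a guanine Hoogsteen edge - the "Hoogsteen
pseudo pair" motif) are grouped per residue pair.

## Nucleic-acid geometry

`backbone_torsions()` computes the standard α, β, γ, δ, ε, ζ
dihedrals and the glycosidic χ (O4'-C1'-N9-C4 for purines,
O4'-C1'-N1-C2 for pyrimidines). A torsion whose quadruple needs an
unmodeled neighboring nucleotide is `NA`, never zero. The syn/anti
boundary is the standard |χ| ≤ 90° window for syn.

`detect_base_pairs()` nominates a pair when (i) the bases form at
least two heavy-atom hydrogen bonds among edge atoms, at least one per
side involving a base (non-sugar) atom, (ii) the base planes are
within 45° of parallel, and (iii) each base centroid lies within 2.0
Angstroms of the partner's plane. Gate (iii) matters: stacked
sequential bases also have parallel planes and can share sugar-sugar
hydrogen bonds, and coplanarity is what distinguishes pairing from
stacking. Edges are assigned per atom from a fixed Leontis-Westhof
membership table in which atoms bordering two edges (purine N6/O6
between Watson-Crick and Hoogsteen, pyrimidine O2 between Watson-Crick
and sugar) vote for both; the pair-level edge is the majority vote with
ties resolved Watson-Crick > Hoogsteen > Sugar. The cis/trans
orientation is computed from the glycosidic-bond vectors: project both
C1'→N vectors perpendicular to the C1'-C1' axis; same-side projections
are *cis*. This self-contained convention reproduces the textbook
labels on constructed fixtures (canonical pairs are *cis* WC/WC; a
base flipped 180° about the C1'-C1' axis becomes *trans*) without a
reference-frame library.

`stacking_runs_and_flips()` builds maximal runs of sequentially
stacked bases (same gates as the interface module, applied to the 5-
and 6-membered rings separately) and flags a nucleotide as flipped-out
when it stacks with neither sequential neighbor although both are
modeled — the signature of a base turned towards the protein.

`helix_form()` derives a frame per base pair (origin at the C1'-C1'
midpoint, x along C1'→C1', z along the mean base normal) and averages
the per-step rise and twist. Categorical windows follow
fiber-diffraction canon: A-form for rise 2.3-3.1 Å and twist 30-34°,
B-form for rise 3.1-3.6 Å and twist 34-38°, otherwise irregular.

## Dyad pseudo-symmetry

`dimer_dyad_axis()` superposes protomer A onto protomer B and
decomposes the rotation into axis and angle (an eigenvector
construction keeps the axis stable near 180°). Real dimers are never
exactly C2, so the screw component — the residual translation along
the axis — is reported, not absorbed. `rna_self_correspondence()`
then rotates the ligand's phosphorus atoms by exactly 180° about that
axis and maps each rotated phosphorus to its nearest original, keeping
mutual nearest neighbors. Phosphorus atoms are used because they are
the conventional backbone landmark and are insensitive to base
identity; mutual-nearest filtering avoids fabricating correspondences
where the match is poor. For a palindromic duplex bound symmetrically
this table shows uniformly small distances; for a monomeric L-shaped
ligand it shows a few fortuitously close phosphates and divergence
towards the termini — exactly the diagnostic separating "the complex
is two-fold symmetric" from "only the dimer is".

## Binding thermodynamics

`derive_thermo()` applies ΔG = ΔH − TΔS and, independently,
ΔG = RT ln K_d (R = 8.314 J mol⁻¹ K⁻¹, K_d molar). The default
tabulation temperature is **298 K**, not 298.15 K: the package's
bundled parameter table reproduces its printed −TΔS column exactly at
0.1 kJ mol⁻¹ with 298 K, so that is the temperature the derivations
use. The residual between the two ΔG routes is reported, never
hidden: dissociation constants printed to three digits can disagree
with ΔH − TΔS by ~1 kJ mol⁻¹, and that inconsistency is information.
Concentrations refer to the protein **dimer** throughout (one dimer
binds one ligand); `fold_change()` reports the exact K_d ratio plus a
two-significant-figure presentation string, which is how such ratios
are usually quoted.

The calorimetric model (`simulate_itc()`/`fit_itc()`) is the exact 1:1
single-site mass balance: the bound concentration after injection *i*
solves a quadratic in the total macromolecule sites (n·M) and total
titrant, both corrected for the volume displaced by each injection,
and the per-injection heat is the increment in bound complex times the
cell volume and ΔH. The default protocol mirrors a standard
nano-calorimeter run: 300 µL cell at 15 µM ligand, 175 µM protein
dimer in the syringe, 35 injections of 5 µL with a discarded 2 µL
first injection. Fitting is nonlinear least squares over (log K_d,
ΔH, n) via Levenberg-Marquardt with three starting points spanning
five orders of magnitude in K_d; ΔS is derived from the fitted K_d
and ΔH. At a c-value of ~2500 (tight binding), individual noisy
replicates can push K_d to the identifiability boundary — the
simulation study in the tests therefore checks the **median** over
100 seeded replicates, which stays within 15% of truth at 2% heat
noise. `fit_fraction_bound()` fits the hyperbola f = [P]/(K_d + [P])
for mobility-shift titrations recorded with protein in excess over
labeled RNA.

## Synthetic structures: what they emulate and what they do not

The generators exist so that every geometric operation is testable
against constructions with known answers:

* `build_helix()` places idealized Watson-Crick pairs along a straight
  axis at the canonical fiber parameters (A-form: rise 2.81 Å, twist
  32.7°; B-form: 3.38 Å, 36.0°). Base geometry comes from bundled
  idealized nucleotide templates (standard chemical-component
  geometry); the second base of each pair is positioned by
  deterministic least squares on the canonical hydrogen-bond lengths
  (2.9 Å), the C1'-C1' distance (10.4 Å) and the two glycosidic λ
  angles (54.5°), the last of which selects the Watson-Crick branch
  from the mirror solution.
* `build_c2_complex()` pairs a synthetic three-helix Cα protomer
  (deliberately *not* a model of any real protein) with its exact
  180°-rotated copy, and places a duplex with its internal pseudo-dyad
  on the protein dyad (`symmetric`), displaced off it (`offset`), or
  replaced by a bent single strand (`monomeric_L`). Placements that
  bring components within 1.5 Å are rejected.
* `perturb_structure()` adds seeded isotropic Gaussian noise.

Deliberate non-goals of the generators: the sugar-phosphate backbone
follows each base rigidly, so inter-nucleotide backbone torsions of
generated helices are not idealized (torsion code is tested on
explicit four-atom constructions and mirror/rigid-motion properties
instead); there is no propeller twist, no sequence-dependent step
geometry, no solvent. Consequently, green tests on synthetic fixtures
demonstrate correctness of the *geometry operations*, not agreement
with any particular crystal structure. Checks against published
crystallographic quantities require the corresponding depositions
(accessions 6SY4 and 1QPI, plus 3ZQF/2TCT/2NS8 for the conformation
ranking), which are not bundled; the acceptance tests look for them
under `tests/testthat/depositions/` and state plainly when they are
absent.

## Numerical choices and degenerate inputs

* Alternate locations: keep the highest-occupancy conformer; ties go
  to the lexicographically smallest altloc tag. Deterministic and
  standard.
* Author numbering everywhere, because residues are cited by author
  numbers in the literature the reports are compared against.
* Waters and non-polymer ligands are excluded from interface and
  geometry operations unless explicitly selected.
* Selections are order-deterministic (chains in given order, segments
  in given order, residues ascending, atom names lexicographic), and
  unmodeled residues in a requested segment are counted and reported,
  not errors.
* Superposition requires ≥ 3 non-collinear points; dyad extraction
  refuses rotations under 90° ("not an approximate dyad") rather than
  returning a meaningless axis.
* All random operations (noise, simulation) take explicit seeds and
  restore the caller's RNG state.

## Problem sizes

The test suite runs entirely on synthetic fixtures: 8-12 bp helices,
36-residue protomers, 50-point clouds for the superposition oracle, 50
random toys for the census oracle, and 100 seeded calorimetric
replicates; the whole suite completes in well under a minute on one
core. The acceptance script re-derives the thermodynamic table, the
fold-changes, the calorimetric recovery study and the geometric
self-checks from scratch at the same sizes.

## Known limitations

* No sugar-pucker/pseudorotation analysis, no modified nucleotides,
  no secondary-structure prediction.
* Interface areas depend on the radius table and probe; cross-program
  comparisons are ±10% affairs.
* The cis/trans convention is a geometric projection rule; for
  strongly non-planar pairs a reference-frame method could disagree
  near the boundary.
* The calorimetric model is strictly 1:1; cooperative or multi-site
  systems are out of scope.
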