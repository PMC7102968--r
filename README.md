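# aptcomplex

Structural and thermodynamic characterization of complexes between
homodimeric nucleic-acid-binding proteins and their ligands — operator
DNA or synthetic RNA aptamers.

## The problem

A homodimeric repressor such as TetR reads palindromic operator DNA
symmetrically with its two N-terminal DNA-binding heads. SELEX-derived
RNA aptamers can out-compete the operator, yet an RNA hairpin is a
monomeric, asymmetric ligand that cannot adopt B-DNA geometry. Deciding
*how* such an aptamer wins — by mimicking the operator's contacts, by
exploiting the protein's allosteric conformations, or both — requires a
consistent quantitative comparison of the two complexes:

* **Conformation.** Superpose structures on the conformationally
  invariant effector-binding domains (EBDs, pooled over both
  protomers) and measure the r.m.s.d. of the nucleotide-binding
  domains (NBDs) **without refitting**. Small probe r.m.s.d. means the
  reading heads sit in the DNA-binding-competent arrangement; large
  means the effector-induced one.
* **Interface.** Residue census at a distance cutoff (default 3.7 Å),
  Shrake-Rupley buried-surface decomposition per domain, and typed
  interactions: heavy-atom hydrogen bonds (≤ 3.5 Å, antecedent angle
  ≥ 90°), π-π stacking (centroids ≤ 4.5 Å, interplanar ≤ 30°),
  cation-π (≤ 6.0 Å, off-normal ≤ 45°).
* **RNA fold.** Backbone torsions (α…ζ, χ), syn/anti classes,
  base-pair detection with Leontis-Westhof edge and cis/trans
  orientation labels, stacking runs, flipped-out bases, and A/B helix
  calls from mean rise and twist.
* **Symmetry.** Extract the dimer dyad from the protomer
  superposition, rotate the ligand's phosphorus atoms 180° about it,
  and tabulate mutual-nearest P-P correspondences: a palindromic
  duplex maps onto itself; a monomeric aptamer does not.
* **Energetics.** ΔG = ΔH − TΔS and ΔG = RT ln K_d bookkeeping at
  298 K, K_d fold-changes, an exact 1:1 injection-heat model for
  isothermal titration calorimetry (simulate + Levenberg-Marquardt
  refit of K_d, ΔH, n), and a fraction-bound isotherm fit
  f = [P]/(K_d + [P]) for mobility-shift data.

Synthetic-structure generators (ideal A-/B-form helices built from
idealized nucleotide templates, exact C2 toy dimers, seeded coordinate
noise) make every operation testable without downloading depositions.

## Worked example

```r
library(aptcomplex)

## thermodynamic table from tabulated ITC parameters (K_d in nM,
## dH in kJ/mol, dS in J/mol/K), fold-changes vs the wild-type row
tab <- thermo_table(system.file("extdata", "binding_parameters.tsv",
                                package = "aptcomplex"),
                    reference = "rna_wt")
tab[, c("id", "K_d", "dH", "dS", "minus_TdS", "dG", "dG_from_Kd",
        "fold_change")]
#>         id     K_d     dH     dS minus_TdS     dG dG_from_Kd fold_change
#> 1   rna_wt     5.6 -156.0 -365.2    108.83 -47.17     -47.08       1.000
#> 2 rna_q38a    26.2 -152.8 -367.2    109.43 -43.37     -43.25       4.679
#> 3 rna_y42a 13900.0  -74.6 -157.1     46.82 -27.78     -27.71    2482.143
#> 4   dna_wt    51.1   57.7  336.4   -100.25 -42.55     -41.60       9.125
#> 5 dna_q38a   432.7   53.4  300.9    -89.67 -36.27     -36.30      77.268
```

Reading the table: RNA binding is enthalpy-driven (ΔH = −156 kJ/mol
against a −TΔS penalty of +108.8), DNA binding entropy-driven
(ΔH = +57.7, −TΔS = −100.2), yet the overall ΔG values are comparable
(−47.2 vs −42.5 kJ/mol). The `dG_from_Kd` column is the independent
RT·ln K_d route; its residual against ΔH − TΔS (−0.95 kJ/mol for the
DNA row) exposes rounding in the tabulated K_d rather than hiding it.
The fold-change column reproduces the conventional "8.5-fold" (DNA,
Q38A: 432.7/51.1 at two significant figures) and "2500-fold" (RNA,
Y42A) statements via `fold_change()`.

```r
## full structural report on a synthetic C2-symmetric complex
m <- build_c2_complex(toy_complex_spec("GGAUCC", mode = "symmetric"))
rep <- analyze_complex(analysis_config(m, protein_chains = c("A", "B"),
                                       nucleic_chains = c("C", "D")))
rep$symmetry$axis$angle                      # 180.0 deg
max(rep$symmetry$correspondence$table$pp_distance)   # 0.00 A
rep$base_pairs[1:3, c("resno_i", "resid_i", "resno_j", "resid_j",
                      "edge_i", "edge_j", "orientation", "canonical")]
#>   resno_i resid_i resno_j resid_j      edge_i      edge_j orientation canonical
#> 1       1       G       6       C WatsonCrick WatsonCrick         cis      TRUE
#> 2       2       G       5       C WatsonCrick WatsonCrick         cis      TRUE
#> 3       3       A       4       U WatsonCrick WatsonCrick         cis      TRUE
```

A duplex whose internal pseudo-dyad coincides with the protein dyad
maps onto itself perfectly under the 180° rotation; running the same
report on `mode = "monomeric_L"` gives a self-correspondence r.m.s.d.
above 10 Å — the geometric signature separating a symmetric DNA-type
complex from an asymmetric aptamer-type one.

A command-line wrapper for the same operations ships in
`inst/scripts/aptcomplex` (`analyze`, `compare`, `thermo`, `fixtures`
subcommands).

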