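# groovedyn

Conformational and energetic analysis of MHC class I peptide-binding
grooves.

MHC class I molecules present peptides of 8–10 residues to cytotoxic T
cells. The binding groove (the α1/α2 superdomain, residues 1–180) clamps
the peptide at both ends: the A pocket binds the N terminus, the F pocket
buries the C-terminal residue (Pω) and hydrogen-bonds its carboxylate. A
recurring observation in molecular-dynamics and biochemical work on the
mouse allotype H-2K^b^ is that occupancy of the F pocket dominates the
conformational and thermodynamic stability of the groove: without a
peptide C terminus, the helix segments flanking the F pocket fluctuate
like those of the empty molecule, while the A-pocket region barely
changes.

`groovedyn` packages the quantitative machinery of that kind of study as
tested, composable R functions, together with synthetic-data generators
that produce every input with known ground truth. It is aimed at
structural bioinformaticians who have per-frame coordinates, per-frame
energy decompositions, umbrella-sampling window samples or plate-reader
curves in hand and want the downstream statistics — not at running MD or
solving the Poisson–Boltzmann equation, which stay upstream.

## What it computes

**Ensemble statistics** (from multi-model PDB or plain frame tables):

- Kabsch least-squares superposition; per-frame RMSD series
  `RMSD_t = min_{R,t} sqrt(mean_i |R x_i + t − r_i|²)` and pooled RMSD
  probability distributions with kernel-density mode calling;
- per-residue RMSF about the ensemble mean,
  `RMSF_i = sqrt(⟨|x_i − ⟨x_i⟩|²⟩)`, exportable as a B-factor heat map;
- groove **width variance**: for opposing helix segments (Region I =
  residues 50–59/165–176, II = 60–72/152–164, III = 73–84/139–150) the
  per-frame distance `d_t` between Cα centroids, and
  `WV = Var(d_t)` in Å² — the flexibility statistic distinguishing empty
  from loaded grooves;
- single-pass leader clustering at an RMSD cutoff and its cluster-count
  convergence diagnostic.

**Binding energetics**: MM-PBSA-style aggregation
`ΔG = ⟨G_complex⟩ − ⟨G_receptor⟩ − ⟨G_ligand⟩` with
`G = E_int + E_vdW + E_elec + G_polar + G_nonpolar` (no entropy term),
cluster-based standard deviations, and ΔΔG ranking of peptide variants.

**Potentials of mean force**: the WHAM self-consistent equations
`P(ξ_b) = Σ_j n_j(ξ_b) / Σ_j N_j e^{β f_j − β w_j(ξ_b)}`,
`e^{−β f_j} = Σ_b P(ξ_b) e^{−β w_j(ξ_b)}`, with
`W(ξ) = −k_B T ln P(ξ)` anchored at 0, plus barrier comparison between
variants.

**Wet-lab fits**: two-state thermal denaturation (free `Tm`, van't Hoff
`ΔH_m`, linear baselines), the Tm-shift stability change
`ΔΔG_TDTF = ΔH_m,ref · ΔTm / T_m,ref`, four-parameter logistic IC50
competition curves, and exponential cell-surface decay with half-time
`t50`. A cross-method module correlates ΔΔG_TDTF with ΔΔG_MM-PBSA after
reconciling sign conventions.

## Worked example

```r
library(groovedyn)

# 1. synthetic ensembles: an empty groove (flexible F-pocket region) vs a
#    peptide-loaded groove, 2000 frames each
empty  <- gen_groove_trajectory(n_frames = 2000,
                                sd_width = c(I = 0.2, II = 0.3, III = 1.0),
                                jitter_sd = 0.1, seed = 42)
loaded <- gen_groove_trajectory(n_frames = 2000,
                                sd_width = c(I = 0.2, II = 0.3, III = 0.3),
                                jitter_sd = 0.1, seed = 43)
for (reg in c("I", "III")) {
  we <- width_variance(empty$trajectory, reg)
  wl <- width_variance(loaded$trajectory, reg)
  cat(sprintf("Region %-3s WV empty = %.3f A^2 | WV loaded = %.3f A^2\n",
              reg, we$wv, wl$wv))
}
#> Region I   WV empty = 0.043 A^2 | WV loaded = 0.047 A^2
#> Region III WV empty = 1.042 A^2 | WV loaded = 0.093 A^2

# 2. thermal denaturation: fit melting curves and convert the Tm shift
cv_full  <- gen_curve("melting", list(Tm = 328.85, dHm = 120, a_n = 100,
                                      b_n = -0.12, a_u = 35, b_u = -0.05),
                      x = seq(283, 363, 1), noise_sd = 0.8, seed = 7)
cv_empty <- gen_curve("melting", list(Tm = 306.15, dHm = 120, a_n = 100,
                                      b_n = -0.12, a_u = 35, b_u = -0.05),
                      x = seq(283, 363, 1), noise_sd = 0.8, seed = 8)
fit_full  <- fit_melting_curve(cv_full)
fit_empty <- fit_melting_curve(cv_empty)
print(fit_full)
#> melting_fit: Tm = 328.85 K (55.70 C), dHm = 115.5 kcal/mol
print(fit_empty)
#> melting_fit: Tm = 306.17 K (33.02 C), dHm = 122.2 kcal/mol
print(ddg_from_tm(fit_empty, fit_full))
#> ddg_tdtf: ddG = -7.97 kcal/mol (dTm = -22.67 K vs Tm_ref = 328.85 K)
```

The width-variance contrast reads exactly as in groove-flexibility
studies: the F-pocket region (Region III) loses about 0.9 Å² of width
variance on loading while the A-pocket region (Region I) is unchanged.
The melting fits recover the configured midpoints (55.7 °C and 33 °C);
the negative ΔΔG says the low-Tm state is far less stable than the
peptide-loaded reference.

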