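---
title: "Methods: groove dynamics, binding energetics, and stability fits"
author: "groovedyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: groove dynamics, binding energetics, and stability fits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groovedyn)
```

`groovedyn` implements the quantitative core of a combined
computational/experimental workflow for studying how peptide ligands
stabilize the MHC class I binding groove, in particular how occupancy of
the F pocket by the peptide's C-terminal residue (Pω) restrains the
conformational flexibility of the α1/α2 helices. This vignette records
the models, the tunable parameters, the numerical choices, and — just as
importantly — what the synthetic generators can and cannot stand in for.

## Scope and data model

The package consumes, it does not produce, the expensive upstream
artifacts: coordinate ensembles come from an external MD engine (or the
built-in toy generator), per-frame energy components from an external
MM-PBSA pipeline, umbrella-window samples from biased simulations, and
measurement curves from plate readers or flow cytometry. Everything is
exchanged in plain text: fixed-column PDB for structures and multi-model
trajectories, TSV frame tables (`frame, time_ns, atom_index, x, y, z`),
TSV energy tables, a windows manifest plus one sample file per window,
and two-column curve tables. Coordinates are in Å, energies in kcal/mol,
and temperatures are stored in K (`°C` inputs convert at parse time,
`T_K = T_C + 273.15`). Residue numbering is 1-based PDB numbering;
ranges are inclusive.

The analysis scope for all ensemble statistics is the binding groove,
Cα atoms of residues 1–180. Whether the upstream simulations retained
β2-microglobulin or the α3 domain is irrelevant here: selections outside
1–180 are simply never analyzed. Atoms missing from an explicit
selection are an error, never silently skipped — RMSD series are only
comparable over fixed atom sets.

## Ensemble statistics

**Superposition.** All RMSD/RMSF quantities use a least-squares
rigid-body fit (Kabsch, via SVD of the 3×3 covariance of the centered
coordinate sets, with the determinant correction that guarantees a
proper rotation). Collinear selections and selections of fewer than
three atoms are rejected. `rmsd_series()` fits every frame to the
reference (by default the crystal-derived starting structure; the first
frame is one argument away) and is therefore invariant to arbitrary
rigid motions of the frames; a `fit = FALSE` mode reports the plain
coordinate RMSD for closed-form checks.

**RMSD distributions.** Pooled series are binned at 0.1 Å (default)
into a probability histogram; modes are called on a Gaussian kernel
density estimate with Silverman's-rule bandwidth, as local maxima
exceeding 5 % of the global maximum. The threshold exists because noise
in well-sampled tails otherwise produces spurious single-bin modes;
plateau-topped densities contribute one mode, not two.

**RMSF.** Frames are fitted to the first frame, averaged, and refitted
once to that average before fluctuations are taken; further iterations
change desk-scale profiles by less than the sampling noise, so the
single refit is the documented contract. Profiles are ordered by residue
number regardless of atom order in the input file and can be written
onto the structure's B-factor column (`%6.2f`, clamped at 999.99) for
heat-map rendering.

**Width variance.** The groove is split into three pairs of opposing
helix segments: Region I (A-pocket end, residues 50–59 vs 165–176),
Region II (center, 60–72 vs 152–164), Region III (F-pocket end, 73–84 vs
139–150). The per-frame width is the distance between the *unweighted*
Cα centroids of the two segments ("centers of mass" of identical atoms),
computed without superposition since distances are rotation-invariant —
a property the test suite asserts to 1e-10 under random per-frame rigid
motions. WV is the population variance (divide by *n*) of the width
series: the statistic describes the spread of the full ensemble at hand,
not an inference about a longer hypothetical trajectory.

**Clustering.** The trajectory is clustered by the deterministic
single-pass leader algorithm: a frame joins the first existing cluster
whose *founding* frame lies within the RMSD cutoff (default 1.5 Å on the
groove selection), otherwise it founds a new cluster. Leader clustering
was chosen over k-medoids/average-linkage because it is order-stable,
trivially verifiable against a naive reimplementation, and incremental —
the cluster-count convergence diagnostic (count vs cumulative time) falls
out of a single pass and is non-decreasing by construction.

## MM-PBSA aggregation

Each system's frame free energy is
`G = E_internal + E_vdw + E_elec + G_polar + G_nonpolar`, and
`ΔG = ⟨G_complex⟩ − ⟨G_receptor⟩ − ⟨G_ligand⟩` over frames. The entropy
term is permanently excluded (no flag): the package mirrors the common
practice of ranking relative binding strengths without the expensive and
noisy normal-mode term. The uncertainty attached to ΔG is the sample
standard deviation (n−1) across per-cluster mean ΔG values, the clusters
being conformational clusters of the underlying trajectory — an error
model that respects the fact that frames within a conformational state
are far from independent. ΔΔG is `variant − reference`, so destabilizing
C-terminal truncations come out positive and rank last.

## WHAM

`wham_solve()` iterates the standard pair

$$P(\xi_b) = \frac{\sum_j n_j(\xi_b)}{\sum_j N_j\,
  e^{\beta f_j - \beta w_j(\xi_b)}}, \qquad
  e^{-\beta f_j} = \sum_b P(\xi_b)\, e^{-\beta w_j(\xi_b)}$$

in log space (log-sum-exp; bias factors `w_j(ξ) = k_j/2 (ξ − ξ_0j)²`
can reach hundreds of kcal/mol without overflow), with `f_1` pinned to 0
each sweep since `P` is only defined up to a constant. Defaults: bin
width 0.1 Å, tolerance 1e-6 kcal/mol on `max |Δf_j|`, at most 1e5
iterations, T = 300 K, `k_B = 0.0019872041` kcal/mol/K. Non-convergence
is a flagged result with a warning, not an exception. Bins with zero
counts are reported absent (`NA`), never interpolated; queries snap to
the nearest populated bin within one bin width and error beyond that. A
gap of unpopulated bins inside the covered range warns, because WHAM
silently decouples disconnected segments. `W(ξ) = −k_B T ln P(ξ)` is
anchored so its minimum over populated bins is exactly 0, which is also
why `pmf_barrier_difference()` compares barrier heights relative to each
profile's own bound state: adding a constant to a potential before
solving changes nothing, and the tests demonstrate it.

Two caveats worth stating. First, statistical uncertainty of the PMF is
out of scope; the convergence flag plus analytic fixtures (Boltzmann
inversion of a harmonic potential; a double well with known barrier)
stand in. Second, duplicating a window's samples is *not* an invariance
of the WHAM equations: it doubles that window's weight in the pooled
histogram, which shifts the solution whenever the window's empirical
histogram deviates from its model expectation (i.e. always, at finite
sampling). The identity does hold when every window shares one bias, and
the genuine invariance — scaling all bias constants and `k_B T` by the
same factor leaves `P` unchanged — is asserted numerically in the suite.

## Wet-lab fits

**Two-state melting.** The observed fluorescence is
`F(T) = (a_n + b_n T)(1−θ) + (a_u + b_u T)θ` with unfolded fraction
`θ(T) = 1/(1 + exp(ΔG_u/(RT)))` and
`ΔG_u(T) = ΔH_m(1 − T/T_m) + ΔC_p(T − T_m − T ln(T/T_m))`. `ΔC_p` is
fixed at 0 by default (Schellman's linear approximation) and exposed as
an optional input rather than fitted: desk-scale curves cannot constrain
it. `T_m` and `ΔH_m` are free; initialization is deterministic — `T_m`
at the steepest descent of a lowess-smoothed curve, baselines from the
extreme deciles, with a coarse `T_m`/`ΔH_m` grid retry — so the fitter
is reproducible without random restarts. At least 12 points spanning the
transition are required; a curve whose extreme-decile span does not
exceed five noise SDs is rejected as flat.

**ΔΔG from the Tm shift.** `ΔΔG = ΔH_m,ref · ΔT_m / T_m,ref` (plus the
Gibbs–Helmholtz `ΔC_p` correction when supplied), i.e. the reference
unfolding free energy evaluated at the variant's midpoint, with the
reference enthalpy taken from the reference *fit*, not a literature
constant. The sign convention is: destabilized variants are negative.
`correlate_ddg()` flips this to the MM-PBSA orientation (destabilized =
positive) before computing Pearson's r, so a perfect cross-method
agreement appears as r → +1; Spearman's rank correlation is reported
alongside as a robustness check. A non-positive reference `T_m` errors
immediately — it is the signature of a Celsius value passed as Kelvin.

**IC50.** Four-parameter logistic
`A(c) = A_lo + (A_hi − A_lo)/(1 + (c/IC50)^h)`, fitted on log
concentration with Hill slope free (initialized at 1, not constrained to
it). Preconditions: ≥ 6 points spanning ≥ 2 orders of magnitude; all-
plateau data are a no-inhibition error; non-monotonicity beyond the
noise level warns but does not abort.

**Surface decay.** `N(t) = N_∞ + (100 − N_∞) e^{−kt}` for percent of
initial surface signal; `t50` is the time at which the *fitted* curve
crosses 50 % and is reported absent when `N_∞ ≥ 50` — a plateau above
half-maximum means the molecule population never decays that far, which
is itself the result. A constant series degenerates gracefully to
`k = 0`.

All fitters go through Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`) and are deterministic given data and settings.

## The synthetic generators

The generators exist so that every pipeline stage is testable against
known ground truth with no external data.

- **Toy groove** (`toy_groove_structure()`): 180 Cα atoms; the two
  helix stretches carrying the region segments run antiparallel 10 Å
  apart over a flat sheet. `gen_groove_trajectory()` displaces each
  region's two segments in opposite directions along the axis joining
  their reference centroids by half of an Ornstein–Uhlenbeck width
  fluctuation (stationary SD `sd_width[r]`, correlation time `tau`,
  default 20 frames), plus isotropic per-atom Gaussian jitter.
  Displacing along the centroid axis (rather than a fixed lab axis)
  makes the configured SD map onto the centroid-distance SD exactly, so
  width-variance recovery is a clean parameter-recovery test. The OU
  process gives the ensemble realistic autocorrelation, which is what
  makes the clustering convergence diagnostic non-trivial. Defaults for
  the "empty vs loaded" contrast: `σ_III = 1.0` vs `0.3` Å with
  `σ_I = 0.2` Å held equal — the F-pocket-dominated flexibility pattern
  by construction.
- **Umbrella windows** (`gen_umbrella_windows()`): Metropolis sampling
  of `U(ξ) + k/2 (ξ − ξ_0)²` with Gaussian proposals (default step
  0.3 Å), 10 % burn-in discarded, acceptance below 5 % warns. Metropolis
  rather than Langevin because its stationary distribution is exact,
  so closed forms (`Var ξ = k_B T/(κ + k)` under harmonic potentials)
  verify the sampler itself.
- **Energy tables** (`gen_energy_tables()`): Gaussian per-frame terms
  around configured means; cluster offsets are applied to the complex
  van der Waals term so each cluster's ground-truth ΔG is exactly
  `ΔG₀ + offset`.
- **Curves** (`gen_curve()`): the three fit families with homoscedastic
  Gaussian noise; the truth (including seed) travels as an attribute and
  in the TSV writers' comment headers.

Every generator requires an explicit seed, is bitwise-reproducible from
it, and restores the caller's RNG state.

**What passing tests do and do not show.** The generators emulate the
*statistical structure* of the real inputs — region-dependent width
fluctuations with temporal correlation, Boltzmann statistics under a
declared 1-D potential, cluster-structured energy noise, two-state /
logistic / exponential response shapes with instrument-like noise. They
do not emulate realistic groove geometry, force-field energetics,
anharmonic couplings between regions, heteroscedastic or drifting
instrument noise, or peptide-sequence dependence. Parameter-recovery
results therefore validate the *estimators and bookkeeping*, not any
claim about real H-2K^b^ ensembles; nanosecond-scale explicit-solvent
observables (RMSD peak positions, absolute PMF barriers, experimental
Tm/IC50 values) are inputs one measures, not outputs this package could
predict.

## Problem sizes and numerical tolerances in the test suite

The suite runs the statistics at sizes chosen to keep parameter-recovery
checks comfortably inside their tolerances: 5·10³ frames for
width-variance recovery (a single-run WV estimate at `τ = 20` carries a
sampling SD near 10 %, so the 15 % recovery band is a ~1.2 σ check —
individual draws can and occasionally do land outside it), 10⁵ samples
for the harmonic Boltzmann-inversion RMSE, 12 windows × 2·10⁴ steps for
the double-well barrier, 100 and 50 noisy replicates for the Tm and IC50
recovery means. Brute-force oracles (rotation-grid superposition, naive
leader clustering, two-pass cluster SD, a scalar-loop WHAM) are kept in
the test helpers, deliberately outside the package code paths they
check.

## Known limitations

- 1-D reaction coordinates only; no MBAR, no decorrelation analysis of
  window samples.
- No per-residue energy decomposition and no entropy estimates beyond
  the RMSF proxy.
- The concentration dependence of Tm for weak binders is handled as
  repeated independent melting fits; no ligand-linkage thermodynamic
  model is fitted.
- Binary trajectory formats are out of scope; convert to multi-model
  PDB or the frame-table dialect upstream.
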