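---
title: "Predicting protein flexibility from graphlet degree vectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein flexibility from graphlet degree vectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Atomic flexibility — the root-mean-square fluctuation (RMSF) of each atom
around its average position in a molecular-dynamics trajectory or an
experimental ensemble — is tightly coupled to local packing: tightly caged
atoms move little, loosely packed ones move a lot. `gdvflex` quantifies
local packing purely from coordinates. A structure is converted into an
atomic contact graph $G = (V, E)$ whose nodes are the protein heavy atoms
and whose edges join every atom pair closer than a cutoff (7 Å by default).
For each atom the package counts how often it occupies each of the 15
automorphism orbits of the 9 connected graphlets on 2–4 nodes — the
graphlet degree vector (GDV). Orbit 0 is the plain degree; higher orbits
(path ends and middles, star leaves and centres, cycle, tailed triangle,
diamond, complete graph) resolve *how* the neighborhood is wired, not just
how large it is. Counting is induced: a triangle is never also counted as
a path.

Flexibility is then a linear model in the transformed counts,

$$\widehat{\mathrm{RMSF}}_i \;=\; n + \sum_{k=0}^{14} \beta_k\, O_{i,k},$$

where $O_{i,k}$ is the log-transformed, per-protein standardized orbit
count ($\log(1 + c_{i,k})$, then a z-score per column within the protein;
sample standard deviation, $n-1$). The reference RMSF is transformed the
same way (plain $\log$, since raw fluctuations are strictly positive, then
a per-protein z-score). Both sides therefore live in a normalized log
space: predictions are rank-comparable within a protein but carry no
absolute Ångström scale, and no back-transform is attempted — the
per-protein scale is not recoverable, and evaluation is by Spearman rank
correlation at the Cα atoms, which any monotone rescaling leaves unchanged.

`published_model()` ships the consensus coefficients obtained by averaging
ordinary-least-squares fits across three independent simulation replicates
of a globular-protein training corpus; with standardized target and
features the intercept is 0. `fit_flex_model()` and `cross_validate()`
reproduce the training protocol on any corpus: per-protein transforms,
rows pooled across proteins, OLS, and grouped k-fold cross-validation in
which folds partition *proteins* — atoms of a held-out protein never touch
its training pool.

## Parameters that matter

* **Contact cutoff** (`cutoff`, Å, default 7). Edges require strict
  `d < cutoff`; a pair at exactly 7 Å is not bonded. The coefficients are
  tied to this value — predicting with a different cutoff than the model
  was trained at is not meaningful.
* **Chunk size** (`chunk_size`, residues, default 100) and **surround
  radius** (`surround_radius`, Å, default 15) for the by-parts mode.
  Orbit counts of a node depend only on nodes within three edges, and an
  edge spans less than 7 Å, so nothing beyond $3 \times 7 = 21$ Å can
  affect a node's GDV row. A surround of 21 Å therefore makes the by-parts
  result *bit-identical* to the all-at-once computation; 12–15 Å trades
  small boundary discrepancies for speed and is the practical default.
  Cores are consecutive runs of whole residues in sequence order; the
  environment of a core is every outside residue with any atom within the
  surround radius of any core Cα (residues enter or leave as a unit).
* **Globularity screen**: `globularity_check()` reports whether the radius
  of gyration is below $N^{0.6}$ for $N$ residues and whether $N > 50$ —
  the screen used to assemble globular training corpora. Rg is
  mass-unweighted over the filtered heavy atoms.

## Input handling

The node set is protein heavy atoms only: hydrogens and deuteriums,
waters, and hetero compounds are removed; for alternate locations the
highest-occupancy conformer wins, ties going to the first encountered.
Crystal, cryo-EM and NMR depositions routinely lack hydrogens, so a
heavy-atom graph is the only choice that gives the coefficients a
consistent node set across sources. All retained chains form one graph
unless a chain filter is given. Multi-model files are read as ensembles;
`cmd_predict()` uses the first model with a notice.

For NMR-style ensembles, `superpose_ensemble()` performs least-squares
rigid superposition (Kabsch, with the determinant +1 constraint so a
mirror image is never applied) onto an iteratively refined mean structure
— superpose, re-average, repeat until the mean moves under $10^{-6}$ Å or
10 rounds. The superposition mask defaults to Cα. `rmsf_from_ensemble()`
is the per-atom root-mean-square displacement from the atom's mean
position, and `representative_model()` picks the conformer with minimum
Cα RMSD to the mean (ties to the lowest index) — the natural single-model
input for prediction.

## Numerical choices and degenerate inputs

* Zero-variance feature columns (an orbit constant within a protein) map
  to all-zero z-scores rather than dividing by zero; a constant reference
  profile likewise maps to zeros. Rank-based evaluation is unaffected.
* A rank-deficient pooled design (possible on geometrically degenerate
  corpora) is reported with a warning and solved by the minimum-norm
  least-squares solution via the singular-value decomposition.
* Spearman scores need at least 3 masked atoms; zero variance on either
  side yields NaN with a warning, and NaN scores are excluded from
  summaries with an explicit tally. Whole models carrying undefined
  reference values are excluded the same way in `cmd_eval()`.
* Isolated atoms get all-zero GDV rows. Cross-validation fold assignment
  shuffles protein ids with a user-supplied seed and deals them
  round-robin; all generator randomness flows through explicit seeds and
  restores the caller's RNG state.
* The B-factor channel used for writing per-atom values is clamped to the
  fixed-width PDB range $[-99.99, 999.99]$ and rounded to two decimals.

## What the synthetic generators emulate — and what they do not

`make_helix_structure()` places four pseudo-atoms per residue on an ideal
α-helix (1.5 Å rise, 100° twist, 2.3 Å Cα radius — consecutive Cα–Cα
distances come out near 3.8 Å) with seeded Gaussian jitter;
`make_rod_structure()` extends 3.5 Å per residue along an axis; the
internal compact-cloud generator draws uniform points at protein-like
heavy-atom density (≈ 0.06 atoms/Å³). These reproduce the *packing
statistics* that the GDV sees — realistic degrees and graphlet spectra —
but not chemistry: no side chains, no secondary-structure diversity, no
solvent. A straight model helix is deliberately elongated, so it fails the
$N^{0.6}$ globularity screen for large $N$; the compact cloud passes it.
Passing tests on these fixtures demonstrates the correctness of the
counting, transformation and training machinery, not field accuracy on
real proteins — that claim belongs to the published coefficients and their
original corpus.

`synth_flex_dataset()` builds training sets with *known* coefficients: it
computes real GDVs of generated structures and sets the normalized target
to $X\beta^{*} + \varepsilon$ with Gaussian noise added in the normalized
log space where the model lives. One subtlety is deliberate: the target
transform z-scores per protein and is therefore blind to affine changes of
log-RMSF, so a reference stored as raw positive values can only determine
the coefficients up to the per-protein scale of the latent signal. The
generator hence supports two reference flavours — `"normalized"` (default;
the latent target is stored exactly, so OLS recovers $\beta^{*}$ to
machine precision as noise vanishes, the property the recovery tests pin
down) and `"raw"` (back-mapped by exponentiation, exercising the full
log/z target path; recovery is then approximate but rank-based evaluation
is unchanged). At the test scale used throughout (50 proteins of 125
residues, 500 atoms each), OLS recovers all 15 generating coefficients to
within ±0.05 at noise sd 0.1, and cross-validated mean Spearman falls
monotonically as the noise rises through 0.1, 0.5, 1.0.

## Problem sizes used by the checks

The test suite verifies the fast counter against an exhaustive
induced-subgraph oracle on over a hundred seeded Erdős–Rényi graphs
($n \in [5, 40]$, $p \in \{0.1, 0.3, 0.5\}$), checks the by-parts/all-at-once
identity on a 3000-atom synthetic structure, and runs the recovery and
cross-validation experiments at 50 proteins × 500 atoms. These sizes were
chosen so the full pipeline — including its brute-force oracles — runs
comfortably on a laptop while still exercising every code path at
realistic graph densities.

## Known limitations

The GDV is local by construction (three edges, 21 Å): slow collective
motions escape it. Highly elongated rod-like architectures — helix bending
of coiled bundles — are the documented failure mode, and inter-domain
hinge motions are compressed because the model sees only local contact
density. Structural errors in the input propagate directly: a mispacked
tail raises local density and suppresses the predicted flexibility around
it. Predictions are normalized; if absolute Ångström values are needed,
they must be calibrated externally per protein.
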