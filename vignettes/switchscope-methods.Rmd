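---
title: "Methods: trajectory analysis of switch-II pocket inhibitor resistance"
author: "switchscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory analysis of switch-II pocket inhibitor resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchscope)
```

## The scientific problem

Covalent inhibitors of KRAS G12C (sotorasib/AMG510, adagrasib/MRTX849) bind
the switch-II pocket, but second-site mutations (K16T, R68S, Y96C, Y96D)
arising on the G12C background confer clinical resistance. Explaining that
resistance from molecular dynamics trajectories requires several distinct
analyses: binding thermodynamics (how much affinity is lost), conformational
kinetics (how the switch loops open and close), interaction structure (which
residue contacts are weakened), and allosteric communication (how signals
reroute through the residue network). `switchscope` implements this whole
chain as a tested, reusable pipeline, and pairs it with a coarse-grained
synthetic system generator whose ground truth is known exactly, so that
every stage can be validated by parameter recovery rather than by eye.

## The synthetic system generator

Real KRAS trajectories (tens of microseconds of all-atom MD) are not
reproducible at desk scale, and no deposited trajectories exist for this
study design. The generator therefore emulates the *structure* of the
problem rather than its atomic detail:

* one coarse-grained bead per protein residue (70 by default), laid out on
  an idealized helix with 3.8 Å spacing, standing in for both the Cα and
  the residue's only heavy atom;
* two loop regions — `LoopI` (residues 30–42) and `LoopII` (57–63) — that
  jump between a *closed* reference and an *open* reference displaced 8 Å
  along the helix axis. The region table is configuration because the
  source literature itself uses slightly different ranges in different
  sections; the defaults follow the ranges used for the free-energy
  surfaces;
* a 10-atom rigid ligand bound beside LoopII, carrying an aromatic
  hexagon, an H-bond donor, an H-bond acceptor, a cationic center and a
  hydrophobic tail, each *planted* at designed distances (H-bonds at
  2.9 Å, salt bridge at 3.4 Å) from typed pocket residues so the
  fingerprint rules fire by construction, far from their thresholds;
* a 4-atom nucleotide analogue with a C1′ reference atom, and one divalent
  ion;
* a covalent link bond between the ligand tail and a pocket-adjacent
  residue (56 by default), emulating the warhead attachment of covalent
  inhibitors and exercising the covalent energy term.

Hidden-state dynamics are a discrete-time Markov chain, not Langevin
dynamics: each frame is the current state's reference coordinates plus
isotropic Gaussian noise. This is deliberate — it gives *exact* ground
truth for Markov-model recovery (the generator matrix), for designed
contact frequencies (stationary-weighted state indicators), and for
interaction frequencies. One integer seed drives everything through a
counter-based splitting scheme (`split_seed`), so the hidden-state stream
and the noise stream can be regenerated independently.

What the generator does **not** emulate: force-field energetics driving
the dynamics, solvent, anisotropic fluctuations, correlated loop motions
beyond the two-state switching, or realistic KRAS geometry. Passing
recovery tests on this system therefore demonstrates the *correctness of
the estimators*, not the realism of any particular KRAS simulation.

## Geometry

Superposition is the standard Kabsch SVD construction with reflections
rejected; it is cross-validated against an independent quaternion (Horn)
implementation to 1e-8 Å on random instances. RMSF uses one re-superposition
pass onto the mean structure — iterating to convergence changes values far
less than the 2 Å flexible-residue gate, which is applied with strict
inequality. A small systematic effect worth knowing about: the rigid-body
fit absorbs 6 degrees of freedom, so the RMSF of N iid-noise atoms is
deflated by a factor of about sqrt(1 − 2/N); at the 70-bead default this is
1.4% and irrelevant to the gate.

The switch-conformation classifier (`classify_switch_state`) is
deliberately threshold-configurable: the conformational "type A / type B"
percentages in the source analysis are defined by zones in the
(Loop I, Loop II) RMSD plane that are not published, so the classifier
takes explicit rectangular zones and refuses overlapping ones.

## Energetics

The binding free energy ledger is

&nbsp;&nbsp;ΔG_cal = ΔE_elec + ΔE_vdW + ΔE_covalent + ΔG_solv − TΔS = ΔE_bind − TΔS

computed with the single-trajectory protocol: complex, receptor and ligand
are scored on identical frames, so ΔX = X_complex − X_receptor − X_ligand.
Constants: Coulomb 332.0637, GB prefactor 166.03, interior dielectric 1,
solvent dielectric 78.5, probe 1.4 Å, surface tension γ = 0.0072
kcal/(mol·Å²), T = 310 K, no distance cutoffs (rescoring convention).

* **Electrostatics / vdW** are plain pairwise sums with Lorentz–Berthelot
  combination. Cross pairs separated by one bond go to the covalent term
  (as the bond's harmonic energy); 1–3 pairs are excluded; 1–4 pairs are
  included at full strength *in the covalent term*, following the ledger
  convention that covalent and 1–4 terms ride together. For a noncovalent
  receptor/ligand split the covalent term is exactly zero.
* **Polar solvation** is Still's generalized Born with self terms,
  f_GB = sqrt(r² + R_iR_j·exp(−r²/4R_iR_j)), over all ordered pairs. For a
  single ion it reduces to the Born formula; at large separation it
  reduces to Born self terms plus the screened pairwise Coulomb term
  (the exact r→∞ limit), which is how the analytic-limit test is posed.
* **Nonpolar solvation** is γ·SASA with Shrake–Rupley sphere sampling on a
  deterministic golden-spiral point set (960 points per atom by default;
  an isolated sphere is exact at any point count because every point is
  exposed).
* **Entropy** is normal-mode analysis on frames minimized under the toy
  vacuum model (harmonic bonds + LJ/Coulomb with 1-2/1-3 exclusions):
  mass-weighted Hessian by central differences of the analytic gradient,
  up to six near-zero rigid-body modes removed (five for linear
  molecules), quantum harmonic-oscillator entropy per remaining mode. The
  rigid-mode gate scales with the stiffest eigenvalue because
  finite-difference noise grows with stiffness. NMA is computed on a small
  number of frames (the published protocol used 50 snapshots for the same
  cost reason); the pipeline default keeps entropy off unless requested.
* **Per-residue decomposition** assigns every cross pair's vdW,
  electrostatic and GB-polar term to the protein residue of the pair; with
  geometry-independent Born radii the GB cross sum is exactly the polar
  ΔG, so residue totals conserve the whole-system cross terms to 1e-6.
  The nonpolar column is the residue's own surface burial.

IC50 values convert to experimental binding free energies via
ΔG_exp = RT·ln(IC50 in molar) at 310 K, and calculated-vs-experimental
agreement is reported as the squared Pearson correlation; recomputing the
published correlations from the published tables shows they are r², not r
(0.706 and 0.954 against printed 0.70 and 0.95).

The published component tables are shipped as plain-text data
(`kras_affinity_tables()`) and treated as *inputs*: the package recomputes
the derived columns from them. Two published quirks are handled explicitly:
the component columns of the first table do not re-sum to the printed
ΔE_bind (so only the footnote identities are asserted), and one column of
the second table (Y96D) is internally inconsistent between ΔE_bind − TΔS
and the printed ΔG_cal; the printed ΔG_cal is taken as authoritative
because the text and the ΔΔG column both agree with it.

## Markov state models and transition path theory

Featurization superposes every frame on the *rigid* (non-flexible)
residues and concatenates the 3D coordinates of the flexible ones
(RMSF > 2 Å). Clustering is k-means with an own k-means++ seeding for
determinism under a fixed seed; `k` and the lag are configuration
(desk-scale defaults k = 100 or smaller; the literature-scale k = 5000 is
reachable by config but pointless on the toy). The published criterion for
choosing 10–14 metastates per system is unstated, so the metastate count is
user-set with default 2 (the toy truth).

Estimation uses sliding-window counts, optional reversible symmetrization
C ← (C + Cᵀ)/2 (a deterministic approximation to maximum-likelihood
reversible estimation — adequate at toy scale and documented as such),
restriction to the largest connected set, and row normalization. Implied
timescales are −lag/ln λ. Coarse-graining is a PCCA-style inner-simplex
construction on the dominant right eigenvectors with crisp argmax
assignment.

TPT computes the forward committor from the standard linear system, the
backward committor from the time-reversed chain, gross flux
f_ij = π_i q⁻_i T_ij q⁺_j and net flux f⁺ = max(0, f − fᵀ). Pathways come
from iterative bottleneck decomposition (remove the max-bottleneck path's
flux until the residual falls below 1e-8 of the total); ties are broken by
shortest, then lexicographically smallest state sequence, and the whole
decomposition is verified against exhaustive simple-path enumeration on
small chains. Dominant states are the shortest pathway prefix whose
cumulative flux strictly exceeds 60%. Metastate representatives are the 10
frames nearest the π-weighted metastate center in feature space; the start
state is the lowest mean-loop-RMSD metastate and the end state the most
populated one, mirroring the published convention.

## Free-energy surfaces

The 2D PMF is Boltzmann inversion of the (Loop I, Loop II) RMSD histogram,
F = −k_BT·ln(count/max count), so the most occupied bin anchors F = 0.
Bins are half-open [lo, hi) with the right-most bin closed (an edge value
belongs to the bin that starts at it); the default grid is 50×50 over the
padded data range. Empty bins are masked, and display values use
max(F) + 1 kcal/mol to avoid infinities. Basins are 8-neighborhood local
minima within a depth threshold (default 1 kcal/mol — unstated in the
source, chosen to separate one-to-three wells on toy surfaces); plateau
ties keep the lowest-index bin so a flat grid yields exactly one basin.

## Interaction fingerprints

The pocket is every residue with a heavy atom within 6 Å of the ligand.
Seven interaction types are implemented (Hydrophobic, HBDonor, HBAcceptor,
PiStacking, Cationic, Anionic, CationPi), named from the ligand's
perspective as in the fingerprint tables being reproduced (HBAcceptor =
the protein donates to a ligand acceptor). The geometric thresholds are
community-standard values — hydrophobic C/S pairs ≤ 4.5 Å; H-bond
donor–acceptor ≤ 3.5 Å with a ≥130° D–H⋯A angle when an explicit hydrogen
exists (the coarse-grained beads carry none, so the distance criterion
governs and planted geometries sit ≥4σ from the threshold); π-stacking
centroids ≤ 5.5 Å with plane angle ≤ 30°, or edge-to-face at 60–90° within
6.5 Å; ionic and cation–π at 4.5 Å. All thresholds are configuration.
Frequencies are percentages of firing frames; the report keeps rows whose
maximum frequency across systems strictly exceeds 30%.

## Dynamic networks

Nodes are protein residues (their bead/Cα), each ligand heavy atom, each
ion, and the nucleotide's C1′ atom. An edge requires the minimum
heavy-atom distance to stay within 4.5 Å in at least 75% of frames, with
sequence-adjacent residues (|i−j| ≤ 1) excluded to stop trivial backbone
paths. Weights are w = −log|C_ij| from the scalar displacement correlation
after superposition, capped at −log(1e-6). Communities come from
Girvan–Newman edge-betweenness removal cut at maximum modularity (igraph's
implementation; weights act as distances). The optimal path is Dijkstra's;
suboptimal paths are *all* simple paths within a weight tolerance,
enumerated exactly by branch-and-bound DFS with shortest-distance-to-sink
pruning, and verified against unpruned enumeration. Per-node path counts
and their between-system deltas reproduce the "signal pathway
increase/decrease" analysis, with the five largest movers flagged.

On the toy system the network is deliberately sparse — helix i,i+3
contacts sit just outside 4.5 Å — so edges concentrate around the ligand
pocket, and the natural source/sink pair for path analysis brackets the
pocket (e.g. `R56` to `R64` through the ligand nodes).

## Pipeline, determinism and problem sizes

`run_pipeline()` executes geometry → MSM/TPT → PMF → fingerprints →
MM/GBSA → network per system, then cross-system tables (affinity ledger
with ΔΔG and r², fingerprint deltas, path deltas against the reference).
Every published constant (310 K, 4.5 Å/75%, 6 Å, 30%, 2 Å, 60%, γ, probe)
is a named `study_config` key with that default. Stage failures are
trapped per system and recorded in a status table; the run manifest
carries the seed and a config hash. For a fixed config and seed the bundle
is reproducible bit-for-bit in its deterministic stages, and the
stochastic stages (generator, k-means) are deterministic given the seed.

Default problem sizes were chosen as the smallest at which each estimator
is statistically comfortable: 50 000 frames for transition-matrix recovery
(sampling error ≈ 0.002 per element), 5 000 frames for frequency recovery
under a fast-mixing chain (occupancy error well under one percentage
point), 10 000 frames for RMSF closed forms, 30–50 scored frames for
MM/GBSA averages, 1e5 samples for the Gaussian PMF check. The MM/GBSA
frame subset mirrors the snapshot-rescoring protocol of the source study
scaled to the toy trajectory length.

## Known limitations

* The generator's Born radii are fixed parameters, not recomputed from
  geometry; GB decomposition exactness depends on that choice.
* Reversible MSM estimation by count symmetrization is biased for
  strongly non-reversible chains; the generator's chains are reversible.
* Entropy by NMA on a toy vacuum model says nothing about real solvated
  entropies; it validates the machinery (frequencies, mode counting,
  partition-function arithmetic) only.
* Coarse-grained beads cannot express intra-residue geometry, so H-bond
  angles apply only where explicit hydrogens exist, and protein aromatic
  rings exist only if a test or user supplies multi-atom residues (the
  data model supports them).
* Community detection inherits igraph's Girvan–Newman behavior of
  selecting the maximum-modularity cut; with distance-like weights the
  modularity uses the same weights, which is the convention of the
  source tooling but debatable on first principles.
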