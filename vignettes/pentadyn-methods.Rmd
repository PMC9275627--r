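---
title: "Models and methods behind pentadyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pentadyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pentadyn)
```

`pentadyn` analyses pentameric ligand-gated ion channels (pLGICs) at
C-alpha resolution. This vignette records the models, the parameters that
matter, the numerical choices, and what the synthetic-data tests do and do
not establish about real data.

## Ensemble PCA and projections

Structures are first reduced to their common residue core — the ordered
intersection of (chain, residue number, insertion code) keys carrying a
CA atom in every member — and rigid-body superposed onto a user-designated
reference with the SVD-based Kabsch algorithm (reflections excluded, so
the rotation determinant is always +1). Core matching is by residue-key
identity, not sequence alignment: the intended inputs are curated
ensembles that share numbering, and a silent alignment fallback would hide
curation errors. The covariance of the superposed coordinates is taken
about the *ensemble mean* with uniform C-alpha weights (no masses — the
representation is already one bead per residue), but projections are
reported relative to the *reference*, which therefore projects exactly at
the origin of the PC plane. These two centres differ; keeping them
distinct is deliberate, since the reference (a closed/apo state) is the
physically meaningful origin while the mean maximizes captured variance.
Mode signs are fixed by requiring the second ensemble member to project
non-negatively — an arbitrary but reproducible convention that stabilizes
plots across runs.

With m members, at most m − 1 eigenvalues are nonzero; variance fractions
are eigenvalues over their sum, and the eigenvalue sum equals the total
coordinate variance (a trace identity the tests assert to 1e-9).

Trajectory frames are each rigid-body fitted to the reference over the
core before projecting. This removes global drift and is standard
essential-dynamics practice; its one subtlety is that deformations with a
net rigid-rotation component (a pure quaternary twist, for instance) lose
that component to the fit, so the essential mode of a noise-free twist
interpolation is the *internal* part of the motion. The exact
"one nonzero mode" identity then holds for displacements orthogonal to
the rigid-body space, and the test suite checks both situations
explicitly.

## Free-energy landscapes

Projected samples on (PC1, PC2) are binned on a 50 × 50 grid spanning the
data range padded by 5%, and converted to ΔG = −kT ln(P/P_max), so the
most populated bin sits at exactly 0. Empty bins are masked (NA) rather
than assigned infinite energy: a finite sample says nothing about how
unfavourable an unvisited bin is. Energies are reported in kT and in
kJ/mol (kT = 2.494 kJ/mol at the default 300 K). The Gaussian-sampling
test recovers the quadratic closed form to 0.1 kT after averaging over
iso-energy shells; individual bins with ~100 counts carry ~0.1 kT of
counting noise on their own.

## Elastic networks

The network potential is harmonic in pair distances,
E = ½ Σ K_ij (R_ij − R⁰_ij)², which makes K_ij the literal spring
constant and gives the standard anisotropic-network Hessian super-blocks
H_ij = −K_ij (r̂ ⊗ r̂) at the minimum; a finite-difference test
differentiates this energy directly and matches the analytic Hessian to
1e-5. Two force fields are provided:

- **cutoff**: uniform K (default 1 kcal/mol/Å²) for all pairs within a
  cutoff (default 10 Å);
- **edenm** (default): sequence neighbours with separation s ≤ 3 in a
  chain get K = C_seq/s² with C_seq = 60 kcal/mol/Å², and all other pairs
  within 12 Å get K = (c/R⁰)⁶ with c = 6 Å — unit stiffness at 6 Å
  decaying with the sixth power of distance, the shape of MD-calibrated
  network force fields. All four constants are arguments.

A connected, non-collinear 3D network has exactly six zero modes;
`normal_modes()` enforces this and treats any other count as a symptom of
a disconnected or mechanically floppy network. The zero tolerance is
1e-9 of the largest eigenvalue: rigid-body eigenvalues land at machine
precision (~1e-14 relative) while the softest genuine modes of a
coarse-grained pentamer sit around 1e-6 relative, so a looser tolerance
would swallow real physics. Strictly collinear systems (the two-bead
closed-form test) have five rigid modes and pass `n_zero_expected = 5`.
Graph connectivity does not imply mechanical rigidity — a 10 Å cutoff on
a sparse coarse-grained fold can leave hinge mechanisms with exactly zero
energy — which is why the cutoff force field's cross-check in the
acceptance tests uses 12 Å on the toy pentamer.

Residue fluctuations come from the Hessian pseudo-inverse restricted to
nonzero modes: MSF_i = kT · tr(H⁺)_ii, with cross-correlations
normalized by the geometric mean of the diagonal blocks. The tests verify
this against a direct generalized inverse and the 1/c scaling law under
uniform spring scaling.

## Overlap metrics

A transition vector is the normalized 3N coordinate difference after
optimal superposition; its pre-normalization magnitude equals
RMSD · √N. Because ENM mode sets exclude the six rigid-body directions,
residual rigid components (numerically tiny after the fit, but nonzero)
are projected out of Δr before normalizing — otherwise they would count
as unexplainable direction. Per-mode overlap uses the absolute cosine
(mode signs are arbitrary), and the cumulative overlap δ(M) is the root
sum of squares over the first M modes, non-decreasing in M and equal to 1
on a complete basis. M = 10 is the reporting default.

## Channel descriptors

All descriptors assume the pore axis along +z; `orient_pore_axis()`
aligns the principal inertia axis of the TMD (the covariance eigenvector
whose eigenvalue is most separated from the other two — the two in-plane
eigenvalues of a C5 bundle are nearly degenerate) with +z, pointing
toward the ECD. Every descriptor is invariant to rotation about z and to
translation.

- **Quaternary twist**: per subunit, the signed XY angle between the
  overall-CM→TMD-CM and overall-CM→ECD-CM directions, right-handed about
  +z, averaged over subunits with a circular mean (plain means misbehave
  at the ±180° wrap).
- **Blooming**: half the maximum pairwise distance among the subunit tip
  residues (for five tips on a circle of radius R this is R sin 72°, the
  long pentagon chord), with the maximum axis distance as a configurable
  alternative. The halved-chord reading of an ambiguous definition is the
  default; recovery tests use the axis variant, for which a programmed
  radial expansion of b Å moves the measure by exactly b.
- **TM2 tilt/twist**: the helical axis is estimated by the bisector
  cross-product construction, which is exact on ideal helices of any
  length; the principal axis of the coordinates is *not* used because the
  helical winding biases it by ~2° on an 18-residue helix, four times the
  recovery tolerance. The axis is expressed in a per-subunit frame with X
  radial (protein CM → helix CM, in-plane), Z the pore axis, Y = Z × X;
  tilt is the signed XZ-projection angle from Z (outward positive), twist
  the YZ-projection angle.
- **Pore profile**: at each z slice (0.5 Å steps, slab half-width = step)
  the radius is the largest clearance min(‖xy − c‖) − r_atom over circle
  centres c, maximized over a bounded box (±4 Å about the axis — outside
  the helix ring the clearance grows without limit, so the search must be
  bounded) on a 0.1 Å grid with two clamped refinement passes down to
  0.004 Å. The clearance landscape is multimodal, so a coarse-then-local
  search can otherwise get trapped ~0.1 Å below the optimum; the fine
  global pass keeps the profiler within 0.01 Å of a 0.025 Å brute-force
  grid oracle. The C-alpha effective radius defaults to 1.9 Å
  (united-atom scale). Fully blocked or empty slices are masked. Gate
  radii average the profile over ±2.5 Å around the gate residues' CM z.
- **Hydration / permeation**: waters are counted inside a configurable
  cylinder (default radius 8 Å, z bounds the TM2 extent ±2 Å — the
  boundary is a modelling choice, stated rather than inherited). A
  permeation event requires entering through one z boundary and exiting
  through the opposite one without leaving the cylinder laterally;
  lateral excursions reset the transit, so an ion drifting in and out of
  the pore mouth never counts.

## Trajectory analysis

GROMOS-style clustering computes the pairwise-fitted RMSD matrix and
repeatedly extracts the frame with the most neighbours within the cutoff
(ties to the lowest frame index, making the partition deterministic);
cluster sizes are non-increasing by construction. Helicity uses a
C-alpha-only criterion — d(i, i+3) in [4.5, 5.5] Å and the virtual
dihedral in [35°, 65°], both satisfied by ideal alpha geometry and
neither by extended chain — as an explicit stand-in for backbone-based
definitions that need atoms a C-alpha model lacks. Polar contacts fall
back to C-alpha proxy distances (8 Å) when side chains are absent, and
omit the H-bond angle criterion when hydrogens are absent; the output
records which mode was used.

## The synthetic generator

The toy pentamer is five copies of one subunit under exact 72° rotations:
an ECD modelled as a single ideal helix (rise 1.5 Å/residue, 100°/residue,
C-alpha radius 2.3 Å — textbook values) leaning outward to a tip, and four
vertical TM helices with TM2 at 8 Å from the pore axis. The TM bundle
spacing was chosen so that the closest non-sequential bead contact is
~4 Å, matching real C-alpha packing and keeping spatial spring constants
physical. ECD and TMD centre-of-mass azimuths are aligned exactly at
construction so that a zero programmed twist measures as zero. Defaults
(28 ECD + 4 × 18 TM residues = 100 per chain, 500 total) keep every
eigenproblem dense-solvable in seconds.

Deformations are applied with known magnitudes — ECD rotation about z
(twist), radial push (bloom), TM2 rotation about its own centre with the
axis target set so the programmed tilt/twist angles are recovered exactly
under the measurement convention — and isotropic Gaussian noise is added
last, independently per coordinate, matching the error model PCA assumes.
Ground truth (including the on-axis minimum pore radius of the noise-free
geometry, which by C5 symmetry is the global optimum) is recorded before
noise.

What passing these tests shows: the estimators are unbiased and exact on
geometry they fully control, the oracles and implementations agree, and
signal recovery behaves as designed under isotropic noise. What they do
not show: robustness to the things real structures add — missing
residues beyond what the core machinery handles, heteromeric chain
mapping, anisotropic and correlated coordinate error, non-ideal helices,
side-chain effects on pore dimensions (a C-alpha profile with a 1.9 Å
probe approximates but does not equal an all-atom HOLE profile). The
deterministic ensemble workflow (`ensemble_report()`) applies unchanged
to downloaded experimental structures, where those effects then matter.

## Problem sizes and seeds

The test suite and the acceptance script run entirely on generated data:
descriptor recovery sweeps a 5 × 5 × 5 grid of programmed deformations;
ensemble analyses use 33 members (3 states × 11 replicas, 0.3 Å noise);
the ED meta-trajectory uses 200 frames at 0.1 Å noise; clustering oracles
use 48–50 frames; hotspot recovery repeats 50–100 seeded draws. These
sizes make every run deterministic and fast while keeping each statistic
well away from its decision threshold. All generator functions take
explicit seeds, and identical seeds reproduce outputs bit-for-bit.

## Known limitations

- Core matching requires shared residue numbering; no sequence-alignment
  fallback is provided (by design — see above).
- The heteromeric chain-mapping question is left to the user: mutation
  tables are consumed as already mapped to structure positions.
- Pore profiles promise tolerance-level agreement with inscribed-circle
  geometry on C-alpha atoms, not bit-parity with the HOLE program.
- The sequence-calibrated force-field constants are configurable defaults
  calibrated for shape, not fitted to any specific protein family.
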