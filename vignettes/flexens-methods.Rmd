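---
title: "Simulating near-native protein flexibility with flexens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating near-native protein flexibility with flexens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexens)
```

# The problem

A crystallographic or NMR structure is a snapshot; the biologically relevant
object is the ensemble of conformations the protein visits around it.
`flexens` estimates that ensemble cheaply: a coarse-grained representation of
the chain is perturbed by small local Monte Carlo moves under a potential
that keeps it near the input structure, and the resulting trajectory is
summarized as a per-residue fluctuation profile and a small set of
representative models. The target of the simulation is *near-native*
dynamics — relative flexibility of loops, termini and secondary-structure
elements — not folding, unfolding or large functional transitions.

# The coarse-grained model

Each residue carries up to four interaction centers: the Cα atom (the only
degree of freedom that is sampled), the Cβ atom, the side-chain center and
the midpoint of the Cα–Cα pseudo-bond. During simulation the dependent
centers are derived deterministically from local Cα geometry (Cβ along a
direction built from the two chain-neighbour vectors; the side-chain center
on the Cα→Cβ ray at a residue-type-specific distance; midpoints exactly),
so the energy is a pure function of the Cα trace. When the input provides
side-chain heavy atoms, `build_cg()` records their centroid as the
side-chain center of the native structure (for alanine that is exactly Cβ);
glycine has no side-chain center of its own and uses its virtual Cβ for
excluded-volume purposes only.

## Energy function

`evaluate_energy()` sums five weighted components (reduced energy units,
distances in Å; every number below is a default of
`default_energy_params()` and can be overridden):

* **Short-range conformational preferences.** Harmonic pseudo-bond term
  about 3.8 Å (k = 5); flat-bottom wells on the pseudo-bond angle and
  pseudo-dihedral with windows conditioned on the 3-state secondary
  structure of the residue: helix angles [80°, 105°] and dihedrals
  50° ± 25°, strand angles [110°, 150°] and dihedrals 180° ± 45°, coil
  angles [70°, 160°] with unconstrained dihedrals. The window centers are
  the values measured on ideal helices (≈ 92°, +51°) and extended chains
  (≈ 131°, ≈ 179°). Outside a window the penalty is quadratic in the excess
  (k_angle = 2, k_dih = 1 per rad²).
* **Side-chain contacts.** A distance well: side-chain centers closer than
  4.5 Å contribute a pair-dependent depth taken from a 20×20 symmetric
  matrix built from Kyte–Doolittle hydropathy sums scaled linearly to
  [−1, 0.2], so the most hydrophobic pair is the most attractive and
  strongly polar pairs are mildly repulsive. Solvent is therefore implicit
  in the contact statistics. The original statistical potential is
  context-dependent (orientation-aware); reducing it to a distance-only well
  is a deliberate simplification, and the matrix is replaceable through the
  parameter object.
* **Cα-model hydrogen bonds.** A pair (|i−j| ≥ 3) with Cα distance in
  [4.4, 5.6] Å and |cos| ≥ 0.75 between the local chain directions (unit
  vectors between successive peptide centers) contributes −1. In practice
  this rewards tight extended-extended packing; helices are maintained by
  the short-range wells and restraints rather than by this term.
* **Near-native restraints.** Flat-bottom harmonics on Cα–Cα distances,
  zero within ±1.0 Å of the native distance and k(|d−d₀|−1)² outside.
  `derive_restraints()` creates one for every pair with sequence separation
  ≥ 3 and native distance ≤ 8 Å; k = 1 by default and 2 when both residues
  are in regular secondary structure. These restraints are what makes the
  dynamics near-native: loops, which have fewer contacts within the cutoff,
  fluctuate more, which is the qualitative signal the profile reports.
* **Excluded volume.** A steep quadratic penalty (k = 10) when Cα centers
  of residues with |i−j| ≥ 2 approach below 3.0 Å or side-chain centers
  below 2.5 Å.

The lattice discretization of the original coarse-grained model is not
reproduced; sampling is off-lattice in continuous coordinates, which
preserves the described behaviour and keeps every geometric identity exact
(e.g. the midpoint invariant of peptide centers).

# Monte Carlo sampling

`run_simulation()` draws proposals from a fixed mixture: 80 % single-residue
displacements, 15 % two-residue segment displacements, 5 % terminal-residue
moves; displacement vectors are uniform in a cube (half-width 0.5 Å, 1.0 Å
for termini), so proposals are symmetric and detailed balance holds.
Proposals that would push a Cα pseudo-bond outside [3.2, 4.2] Å are
pre-filtered and counted as rejected; every recorded frame is verified
against the same window. Acceptance follows the Metropolis rule at reduced
temperature T = 1.0. One sweep is n_residues attempted moves; after 100
discarded equilibration sweeps one frame is recorded per sweep until 2000
snapshots — the default trajectory length — have been collected. The RNG is
R's default generator under an explicit integer seed recorded in the
trajectory provenance; the same seed reproduces the trajectory bit for bit.

Temperature, amplitudes, spacing and trajectory length are all `sim_params()`
fields. The defaults give acceptance rates around 0.4 on the bundled
fixtures, comfortably inside the (0.05, 0.95) smoke bounds asserted by the
tests.

# Post-processing

**Fluctuation profile.** Frames are superimposed on their iteratively
computed mean structure by `ml_superpose()` and the profile is
msf_i = (1/M) Σ_j ‖x_ij − x̄_i‖². Superposition uses the variance-weighted
(maximum-likelihood) fit rather than plain least squares: with unit weights
a strongly mobile residue drags the global fit toward itself and 10–15 % of
its motion is absorbed into the rigid-body transform, biasing the profile
low exactly where it matters; downweighting by 1/(σ_i² + ε) removes that
leverage. For M = 2 frames differing by a pure displacement d of one
residue, the definition gives d²/4 at that residue (each frame sits d/2
from the mean).

**Clustering and ranking.** `cluster_frames()` runs classical Lloyd K-means
(`stats::kmeans`) on the flattened superimposed Cα coordinates, initialized
by k-means++ under a recorded seed (an empty-cluster failure is retried with
a fresh k-means++ draw; with k-means++ starts this is rare). Dissimilarity
between frames is the Cα RMSD over the common superposition (no pairwise
refit), so the medoid search and K-means operate in the same metric. Each
cluster is represented by its medoid and ranked by density
size / (1 + mean member-to-medoid RMSD) — populous, tight clusters first;
ties break toward the lower original cluster id so ranking is
deterministic. The default of k = 10 output models is a pragmatic ensemble
size for visual inspection and downstream docking, exposed as a parameter.

**Backbone reconstruction.** `rebuild_backbone()` places C, O and N for each
peptide in a local orthonormal frame built from the quadrilateral of four
consecutive Cα (the trace is extended by one mirrored virtual residue at
each end so termini use the same rule). N sits at its ideal offset from the
following Cα; C is then placed by a two-circle intersection in the peptide
plane so that the Cα–C and C–N bond lengths are exactly ideal for any
pseudo-bond length in [3.2, 4.2] Å — deviations are absorbed by the angles,
never by the bonds; O is placed in-plane opposite N, and Cβ follows by ideal
tetrahedral geometry with L-chirality (verified against experimentally
determined side-chain positions). This analytic rule replaces the original
lookup-library approach; it is deterministic, dependency-free and passes the
geometry audits, but it fixes the peptide-plane tilt to the quadrilateral
plane, which is accurate for helices (Cβ error ≈ 0.4 Å on ideal fixtures)
and cruder for strands, whose true carbonyls alternate out of that plane.
Side chains beyond Cβ and any energy-based refinement are out of scope.

**Superposition.** `kabsch_superpose()` is the closed-form weighted
least-squares fit (SVD with determinant correction, so reflections are never
returned; rank-deficient point sets raise an error rather than an arbitrary
answer). `ml_superpose()` iterates alignment to the mean with weights
1/(σ_i² + ε), mean update and per-residue variance re-estimation until the
mean moves less than 10⁻⁶ Å RMS (cap 50 iterations). The covariance model is
per-residue isotropic — a diagonal approximation of full atom-covariance
treatments — with ε = 10⁻⁴ Å² flooring the weights of invariant residues.
Within each iteration both steps minimize the same weighted objective, which
is therefore non-increasing under that iteration's weights; the trace is
returned and asserted in the tests. The pipeline performs the three standard
tasks: superposition of all models, of models plus the input structure, and
pairwise input-to-model fits reported as an RMSD table.

# Synthetic data

The test suite never downloads structures. `make_structure()` builds chains
from ideal internal coordinates (NeRF construction, trans peptides): ideal
α-helices (φ = −57°, ψ = −47°), extended strands (−139°, 135°), a
helix–loop–helix with a polyproline-II-like linker, poly-alanine chains of
arbitrary length for the validator boundary, and a two-stranded antiparallel
β-hairpin around a type-II′-like turn whose hydrogen-bond register is strong
enough for the secondary-structure assigner to label both strands E.
`make_planted_ensemble()` adds per-residue isotropic Gaussian noise
(known ground truth msf_i = 3σ_i²) and a random rigid transform per frame,
which superposition must remove.

These generators emulate the geometric structure of real data — ideal
secondary-structure geometry, known variance structure, exact rigid-body
nuisance transforms — but not its chemistry: no side-chain packing, no
solvent, no experimental noise, no missing atoms or alternate conformations
beyond what the validator fixtures construct deliberately. Passing tests
therefore certify the algorithms (sampling correctness, estimator
consistency, geometric identities), not the biophysical accuracy of the
default force-field parameters on real proteins.

# Numerical choices and degenerate inputs

* Chain continuity is geometric: C(i)–N(i+1) ≤ 2.0 Å. Author numbering gaps
  with continuous geometry are accepted; outputs renumber 1..L and retain
  the original numbering in metadata.
* Chains shorter than 3 residues get an all-coil assignment; reconstruction
  requires ≥ 4 residues; superposition requires ≥ 3 effective non-collinear
  points and raises a rank-deficiency error otherwise.
* A single-frame trajectory yields an all-zero profile with a warning.
* Coordinates are written as "%8.3f", temperature factors as "%6.2f"
  (columns 61–66); round-tripping through the reader is exact at that
  precision, and identical configuration plus seed reproduces all text
  outputs byte-for-byte (the log differs by timestamps only).
* Energies are evaluated in compiled code; the R surface validates inputs
  (finite coordinates, symmetric pair matrix, positive radii) before
  dispatch.

Problem sizes in the tests — chains of 10–30 residues, trajectories of
60–2000 frames, ensembles of 40–2000 frames — were chosen so the full suite
exercises every code path, including one full-length default simulation,
while remaining quick to run on a laptop.

# Known limitations

* The default parameter set is a documented, physically plausible stand-in
  for statistical potentials fit to structural databases; absolute energies
  and temperatures are in reduced units and are not calibrated against
  experiment. Relative flexibility (the MSF profile shape, loop vs helix) is
  the supported readout.
* Pair interactions are distance-only; orientation dependence of side-chain
  packing is not modelled.
* Backbone reconstruction fixes the peptide-plane tilt; strand carbonyl
  placement is approximate (see above).
* Single chains only; no mmCIF; no network access; side chains beyond Cβ are
  not rebuilt.
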