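---
title: "Subtomogram averaging and the chaperonin state census: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtomogram averaging and the chaperonin state census: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(chapsta)
```

## The problem

Bacterial chaperonins are barrel-shaped double-ring complexes (two stacked
heptameric GroEL rings, about 140 Å wide and 146 Å tall) that fold client
proteins inside a chamber capped by the lid-shaped cofactor GroES.  In
cellular cryo-electron tomograms these complexes appear in two oligomeric
forms — asymmetric "bullets" with one lid (EL–ES₁) and symmetric "footballs"
with two (EL–ES₂) — and in several functional states distinguished by the
conformation of the open (*trans*) ring and by whether the folding chamber
holds an ordered, compactly folded substrate or only diffuse density.

`chapsta` implements the computational chain needed to turn tomograms into a
quantitative census of those states: missing-wedge-aware template matching,
subtomogram alignment and wedge-compensated averaging with Cn/Dn symmetry,
gold-standard FSC resolution estimation, bootstrap-seeded simulated-annealing
multireference classification with consensus retention, and per-tomogram
state statistics.  Because every stage is statistical, the package also ships
a parametric phantom simulator that plants known ground truth into synthetic
tomograms, so that recovery of mixing proportions, aperture geometry and
abundance ratios can be validated end to end.

## Data model and conventions

* **Volumes** are cubic 3D arrays with a physical voxel size in Å.  The
  rotation origin is the voxel at 0-based index `floor(N/2)` on each axis.
* **Orientations** are intrinsic ZYZ Euler angles in degrees
  (`Rz(rot) Ry(tilt) Rz(psi)`, reference frame into particle frame), with
  `tilt` in [0, 180] and the other two in [−180, 180).  This matches the
  convention of common subtomogram-averaging particle tables.
* **The missing wedge** is modeled as a single-axis bowtie: Fourier voxels
  whose angle from the plane orthogonal to the beam (measured in the plane
  perpendicular to the tilt axis, y) exceeds the half tilt range
  (default ±60°) are unsampled.  A 3° cosine apodization softens the edge.
  Each particle's wedge rotates with its orientation hypothesis.
* **Constrained cross-correlation** between two volumes is the normalized
  correlation computed only over the product of their wedge masks (DC
  excluded), after mask-weighted zero-mean normalization under a real-space
  mask.  By Cauchy–Schwarz the score lies in [−1, 1]; identical volumes
  score exactly 1 under any shared support.
* **Resolution** is reported at the 0.143 threshold of the Fourier shell
  correlation between independently refined half-maps, with linear
  interpolation in frequency between one-voxel shells; a curve that never
  crosses the threshold yields the Nyquist value flagged as a bound.

Trilinear interpolation is used for all rotations, with out-of-domain voxels
filled by the volume mean (avoiding sharp edges in correlation).  Binning is
done by Fourier cropping rather than block averaging: block binning displaces
the effective rotation origin by half an original voxel, which measurably
corrupts rotations of binned volumes; Fourier cropping preserves the
`floor(N/2)` center exactly and is bandlimit-correct.

## The phantom generator

`build_species_map()` rasterizes parametric species:

* a double-annulus barrel (outer radius 70 Å, cavity radius 22.5 Å, ring
  height 73 Å per ring) with a 7-fold azimuthal wall modulation (amplitude
  0.15); the two rings stack back to back, so the lower ring's bump pattern
  is the dyad image of the upper — full complexes are exactly two-fold
  symmetric in-plane, which matters when footballs are symmetry-expanded;
* an apical aperture funnel spanning the apical third of the open ring, with
  a narrow (45 Å) or wide (65 Å) diameter — the barrel ends where GroES is
  bound are capped by a 30 Å dome;
* encapsulated substrate: ordered substrate is a compact Gaussian blob
  (σ ≈ 10 Å) centred 20 Å below the chamber midplane ("near the bottom of
  the chamber"); disordered substrate carries the same integrated mass at
  4× the width, with a fresh random position jitter per instance so that it
  washes out under averaging — a one-parameter stand-in for dynamic,
  non-native client conformations;
* narrow *trans*-rings always carry an apical substrate blob on the axis
  (the narrow state is the substrate-acceptor state; an empty narrow state
  is not modeled);
* ribosome-like distractors are bumpy spheres of radius 120 Å with a
  deterministic golden-spiral bump pattern.

`simulate_particle_stack()` and `simulate_tomogram()` apply a random
orientation (uniform over SO(3)), filter with the sample-frame wedge, and add
white Gaussian noise calibrated so that the variance ratio between the
particle envelope and the background equals the configured SNR.  Noise is
added *after* wedge filtering, so the wedge region is noise-filled as in real
reconstructions.  Species mixtures are applied by exact largest-remainder
quota, not Bernoulli draws, so planted proportions are fixed numbers.
Default voxel size is 7.04 Å (twice a typical acquisition pixel of 3.52 Å)
with 48³ particle boxes, chosen to keep the full validation pipeline at
desk scale (minutes, one CPU).  In situ SNR is not well characterized;
the default 0.3 is a calibration choice exposed in the configuration.

What the phantoms deliberately do **not** model: CTF and defocus effects,
tilt-dependent dose, macromolecular crowding, membranes, gold fiducials, or
atomic-level structure.  Passing recovery tests therefore demonstrates the
correctness and statistical behaviour of the algorithms under controlled
conditions, not performance on real micrographs.

## Template matching

`match_template()` scans a low-passed (default 40 Å), wedge-filtered template
over the tomogram at every orientation of a quasi-uniform grid
(golden-spiral axis directions × uniform in-plane steps, reduced modulo the
template's symmetry), using FFT-based locally normalized correlation under a
spherical mask.  Matching runs at 2× binning by default.

Peak extraction uses greedy non-maximum suppression with a physical
exclusion radius.  The automatic score cutoff is estimated from the *left
tail* of the score distribution (quantile-based null location/scale): in a
crowded tomogram the mean, the standard deviation, and even the median/MAD
are inflated by the particles and their correlation halos, so a symmetric
robust estimate fails exactly when matching succeeds.  Everything above
`μ₀ + 3σ₀` is kept (deliberate overpicking, to be cleaned up by later
classification and duplicate removal); when confident peaks above
`μ₀ + 5σ₀` exist, the list is capped at `overpick_factor` times their
number.  Cross-template duplicates are collapsed at the physical contact
distance, keeping the higher-scoring interpretation — this is what removes
the chaperonin template's spurious responses on ribosomes.

## Alignment

`align_particles()` refines orientations and shifts per pass over a
non-increasing binning schedule.  A pass with angular range ≥ 180° performs
a global grid search (rotating the reference, scoring all particles in one
BLAS product under their wedges); narrower passes rotate each particle into
the reference frame and search a local cone of perturbations shared across
particles.  References are re-formed each iteration by wedge-weighted
averaging (Fourier sums divided by summed rotated wedges, floored at 1% of
the maximum), optionally symmetrized.  The mean constrained score is tracked;
two consecutive drops abort the pass, keeping the best state, and
improvements below 1e-4 stop it.

Because a local cone search cannot reach the opposite pole, local passes can
optionally test every candidate composed with the in-plane 180° flip
(`check_flip`).  For polar particles like one-lidded bullets this resolves
the lid-up/lid-down ambiguity, which would otherwise contaminate downstream
classification with mirrored averages.

`gold_standard_refine()` splits the particles into two seeded random halves
refined independently from a common 40 Å-filtered start and reports the FSC
between the half-maps.

## Classification

The classification machinery follows the repeated-bootstrap consensus
protocol:

1. **Seeding.** `bootstrap_kmeans_seed()` forms many wedge-compensated
   averages of particles sampled with replacement (desk default 500
   bootstraps of 50; the full-scale protocol uses 5,000 × 250), extracts the
   voxels under the interior mask as per-voxel-standardized features, and
   clusters them with k-means (k = 2, 10 restarts, best inertia).  Cluster
   references are the multiplicity-weighted particle averages of each
   cluster — averaging the *union* of drawn particles would essentially
   reproduce the global mean, because bootstraps of 50 from a few hundred
   particles cover nearly everyone.  One hard argmax assignment pass then
   turns the weak k-means direction into full-contrast starting references.
2. **Annealed MRA.** `mra_anneal()` iterates: score every particle against
   every class (constrained cross-correlation under the focus mask and the
   particle's wedge; one matrix product per class), then update labels by
   stochastic hill climbing — propose a random other class, accept if it
   scores better, otherwise with probability `exp(-Δ/T)`.  The temperature
   `T_i = temperature_factor · s̄ · (1 − i/n_iter)` decays linearly from a
   score-spread-scaled start (factor 10, 40 iterations by default) to zero,
   so the final iterations are pure hill climbing.  References are
   re-averaged from their members every iteration; an emptied class is
   re-seeded from random particles.  The annealing schedule is this
   package's own definition — the acceptance rule is a standard Metropolis
   step with label memory, chosen over a literal "take the worse class with
   probability exp(-Δ/T)" rule, which at high temperature would invert
   rather than randomize the labeling.
3. **Consensus.** `consensus_classify()` repeats the whole procedure
   (default five times) with independently derived seeds, matches labels
   across runs by maximizing reference-to-reference correlation over label
   permutations (exhaustive, K ≤ 4; exact ties break deterministically to
   the lowest permutation index), and retains only particles labeled
   identically in every run.  Retention is monotone: adding repeats can only
   shrink the retained set.

When classes threaten to separate on missing-wedge orientation instead of
structure — the classic failure mode of subtomogram classification — the
class references can be symmetrized every iteration (`symmetry = "C7"`),
erasing azimuthal wedge memory.  This is used for conformational
classification of the C7 complexes; chamber-occupancy classification keeps
C1 references (the substrate breaks the sevenfold symmetry) and applies C7
only to final, reported averages.

A Gaussian-equivalent low-pass (default 25 Å) applied to the particles
before classification serves as a simple denoising stage, and a cubic
center crop around the region of interest cuts the cost of every scoring and
averaging product.

`focused_classify()` separates narrow from wide *trans*-ring conformations
by recentring every record on the *trans* apical level along its particle z
axis (the same shift composition used for chamber pooling), cropping to a
24³ box, and running consensus classification under a disk-shaped mask
covering the aperture and the apical substrate position, with C7-symmetrized
references.

`register_c7_classes()` brings class maps into a single frame modulo the
sevenfold symmetry by testing all seven multiples of 360°/7 about the axis
and keeping the best-correlating one (ties resolve to the smallest
multiple) — an automatic replacement for what is otherwise a manual
registration step.

## Chamber pooling and signal subtraction

`pool_chambers()` performs C2 symmetry expansion: every football contributes
two records (its orientation and that orientation composed with the in-plane
180° flip), every bullet its lid-bound *cis* ring, and every record is
recentred along its particle z axis by half the inter-ring offset (default:
one ring height, from the phantom geometry) so the chamber of interest sits
at the box center with GroES toward +z and the equator toward −z.
Recentring happens at pooling time for both species — whether to recentre
bullets before or after expansion is immaterial here because the
transformation is per-record and exact.

`signal_subtract()` removes the particle-oriented, wedge-filtered reference
outside a kept region from each subtomogram.  Note a physical caveat: with a
±60° wedge the *kept* density's wedge point-spread function extends well
outside the mask, so the residual outside the kept region is only small when
the full tilt range is sampled; the operator itself is exact (it is linear
resampling plus subtraction).

## The state census

`assign_state()` maps (species × trans conformation × per-chamber occupancy)
onto the taxonomy: free `EL` plus seven GroES-bound states — wide bullets
with unordered (i) or ordered (ii) *cis* chambers, narrow bullets (which by
construction carry *trans*-bound substrate) with unordered (iii) or ordered
(iv) chambers, and footballs with zero (v), one (vi) or two (vii) ordered
chambers.  Football chamber labels form an unordered pair.  Exhaustive
enumeration of the valid label space yields exactly seven bound states.

`census()` tabulates counts per tomogram and condition, pooled proportions,
per-tomogram proportion means (both are reported, since printed abundance
figures can be either), and GroEL:ribosome ratios.  `compare_conditions()`
applies the two-sided Wilcoxon rank-sum test to per-tomogram proportions —
exact enumeration when both groups have ≤ 10 tomograms without ties, the
normal approximation with tie and continuity correction otherwise.  P values
are reported uncorrected for multiple testing, and the number of comparisons
is the caller's bookkeeping.

`aperture_diameter()` operationalizes the ring-opening measurement:
azimuthally average the density over the apical slab of the open ring, then
report twice the radius at which the profile first rises to half the wall
maximum moving outward from the axial minimum.  Starting at the axial
*minimum* (not the axis itself) makes the rule robust to on-axis substrate
density in the narrow state.  The measurement is quantized by the radial
binning of one voxel (7.04 Å); the smoothing of the phantom edge biases it a
few Å inward of the nominal funnel diameter, well within one voxel.

`sp_center_of_mass()` reports the intensity-weighted centroid of
above-threshold density inside the chamber mask, in Å relative to the
chamber center with +z toward the lid; the threshold is a fraction of the
*map* maximum (the wall), so an empty chamber raises a "no SP density" flag
rather than returning the centroid of noise.

## Validation protocols and problem sizes

The `protocol_*()` functions run the full measurement chains at the study
compositions: `protocol_species_split()` (1,000 particles, quota 60:40 or
70:30, SNR 0.3; template matching against a bullet reference over a C7 grid,
flip-aware local refinement, trans-region consensus classification),
`protocol_aperture()` (200 particles per conformation, global-then-local
alignment from a 40 Å start, C7 average, half-max rule),
`protocol_occupancy()` (1,000 chambers at the 40% ordered fraction,
bootstrap-k-means seeding plus annealed consensus MRA), and
`protocol_ribosome_ratio()` (five tomograms planting ribosomes and
chaperonins at a 23:1 quota, dual-template matching with automatic cutoffs
and contact-distance duplicate removal).  These sizes keep each protocol in
the one-to-few-minute range on a single CPU while leaving the statistical
headroom the tolerances require.

## Known limitations

* Focused narrow/wide classification carries a one-sided bias: particles
  whose missing wedge hides the apical discriminating density leak from the
  narrow into the wide class (roughly 10 points at SNR 0.3), and run-to-run
  variability at a few hundred particles is several points.  The aperture
  measurements are unaffected (they use single-conformation cohorts).
* Per-particle wedges are binary masks rotated with the orientation
  hypothesis; no per-tilt exposure weighting or CTF model is included.
* The automatic score cutoff deliberately overpicks; on a tomogram
  containing no particles at all it will still return (low-scoring) peaks.
  Downstream cleanup is part of the design.
* The simulator's realism limits are listed above; absolute resolutions
  measured on phantoms are bounded by the 7.04 Å voxel and the smoothed
  rasterization, not by algorithmic fidelity.
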