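# chapsta

Subtomogram averaging and state census of chaperonin complexes in
cryo-electron tomograms — a desk-scale, fully testable R implementation.

Bacterial chaperonins (GroEL, a double ring of two stacked heptamers, with
its lid cofactor GroES) populate distinct states in cells: asymmetric
one-lid "bullet" complexes (EL–ES₁), symmetric two-lid "footballs"
(EL–ES₂), narrow vs wide conformations of the open *trans* ring, and
chambers holding either compactly folded (ordered) or diffuse (disordered)
substrate protein.  Quantifying those states from tomograms requires a chain
of statistical machinery, all of which this package provides:

- **Missing-wedge Fourier machinery** — single-axis wedge masks, per-particle
  rotated wedges, band-pass filters, Cn/Dn symmetrization, and the
  *constrained cross-correlation* `CCC(a, b) = <W F_a, F_b> / (‖√W F_a‖ ‖√W F_b‖)`
  computed over the shared Fourier support `W`, with shift search;
- **Template matching** — FFT-based locally normalized correlation over
  quasi-uniform orientation grids, non-maximum suppression with automatic
  (left-tail null) cutoffs, deliberate overpicking, cytosol masks, and
  cross-template duplicate removal;
- **Alignment and averaging** — progressive-binning orientation/shift
  refinement under per-particle wedges, wedge-compensated averaging,
  gold-standard half-set refinement with FSC(0.143) resolution estimation;
- **Classification** — bootstrap-average k-means seeding (the 5,000 × 250
  protocol at desk scale), simulated-annealing multireference alignment
  (temperature factor 10, 40 iterations, linear decay to pure hill
  climbing), and consensus retention over five independently seeded runs;
- **Census statistics** — the seven-state taxonomy (i–vii) plus free EL,
  per-tomogram counts and proportions, Wilcoxon rank-sum condition
  comparisons, trans-ring aperture measurement by the azimuthal half-max
  rule, and substrate center-of-mass measurement;
- **A phantom simulator** — parametric barrels, lids, apertures, substrate
  blobs and ribosome-like distractors planted at exact quotas into noisy
  missing-wedge tomograms with full ground truth, used by every test.

File formats: MRC2014 (mode 2) volumes and a STAR-dialect particle table
(`write_mrc()`/`read_mrc()`, `write_particles()`/`read_particles()`).

## Worked example

Simulate a 60:40 bullet:football cohort, run the species-split pipeline
(template matching, flip-aware refinement, consensus classification), and
read off the recovered split:

```r
library(chapsta)
r <- protocol_species_split(n = 300, p_asym = 0.6, snr = 0.3, seed = 42)
r$pct_asymmetric
#> [1] 60
r$retained
#> [1] 300
r$accuracy_vs_truth
#> [1] 1
```

The cohort planted exactly 180 bullets among 300 particles (quota mixing);
the pipeline retained all 300 particles through five-fold consensus and
labeled every one correctly, recovering the planted 60% asymmetric
fraction.  At realistic noise this takes under a minute on one CPU.

Measure the trans-ring aperture of a wide-conformation cohort aligned from
scratch:

```r
a <- protocol_aperture(n = 40, conformation = "wide", snr = 0.3, seed = 4)
a$aperture
#> [1] 64.96646
```

65.0 Å against the 65 Å built into the phantom — within one 7.04 Å voxel,
the stated precision of the half-max rule at this sampling.

A full tomogram pipeline (simulate → match → align → classify → census) is
driven by `run_pipeline()` with a YAML-configurable parameter tree, or from
a shell via the thin wrapper:

```sh
Rscript inst/scripts/chapsta.R all --config config.yaml --out run1
```

## Methods

See the methods vignette (`vignettes/chaperonin-census.Rmd`) for the models,
parameter choices, numerical conventions and known limitations.
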