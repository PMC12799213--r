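---
title: "Quantifying synthetic ribbon-type active zones: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying synthetic ribbon-type active zones: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological problem

Hair-cell ribbon synapses concentrate voltage-gated CaV1.3 channels beneath
an electron-dense RIBEYE scaffold. A minimal way to study what such a
presynaptic machine needs is to rebuild it in a naive cell: HEK293 cells
expressing RIBEYE together with a membrane-anchored Bassoon fragment form
membrane-attached "synthetic ribbons", and co-expression of RBP2 recruits
CaV1.3 channels underneath them. Quantifying such experiments requires a
chain of measurements: segmenting fluorescent puncta in 3D and describing
their size and shape; deciding which puncta in two channels belong
together; scoring how membrane-associated a signal is; correlating pixel
intensities between channels with a significance test; measuring
depolarization-evoked Ca^2+^ indicator signals at chosen sites; extracting
and quality-controlling whole-cell IV relations; and applying a consistent
statistical decision tree. `ribbonquant` implements this chain as
composable, deterministic R functions, together with a synthetic-data
generator so that every stage can be validated against known ground truth
without any raw microscopy data.

## The synthetic-data generator

The generator is the package's testbed: it defines the conditions under
which the analysis stages are validated.

* **Geometry.** An ellipsoidal cell (default semi-axes 3.2 x 3.2 x 2.0 µm)
  is voxelized at the acquisition geometry of the imaging experiments:
  80 x 80 nm pixels in xy and 200 nm z steps. The membrane is rendered as
  the set of voxels within `membrane_thickness` (default 0.16 µm) of the
  ellipsoid surface, computed with an exact Euclidean distance transform
  rather than a mesh.
* **Puncta.** Each punctum is an analytic ellipsoid rendered by occupancy
  antialiasing (3^3 subsamples per voxel), so its integrated intensity
  matches the analytic volume to better than 2%. Membrane-anchored pairs
  (a Bassoon-like punctum under the membrane with a RIBEYE-like punctum
  stacked inward at a configurable surface-to-surface gap) emulate the
  synthetic-ribbon arrangement; placements are validated, and puncta
  declared "membrane" but floating in the cytosol are rejected.
* **Optics and noise.** The PSF is an anisotropic Gaussian with default
  sigma 0.1 µm laterally and 0.25 µm axially — a deliberate simplification
  of confocal optics at this voxel size (the true PSF of the instrument is
  not modelled; neither are bleaching or drift). Noise is
  `Poisson(signal/gain) * gain + Normal(0, read_sd)`, which is sufficient
  for parameter-recovery tests. All randomness flows through the config
  seed; identical configs give byte-identical stacks.
* **Time series.** Stimulus-locked Ca^2+^ signals are phenomenological: a
  hotspot at baseline F0 jumps by `amplitude` at stimulus onset and decays
  exponentially from onset with constant `decay_tau` (`Inf` = plateau).
  The decay-from-onset form reflects that, with 10 mM EGTA in the pipette,
  indicator signal near open channels peaks at onset rather than
  accumulating. Indicator binding kinetics are not modelled — the
  generator makes no claim about Calbryte590 on/off rates.
* **Electrophysiology.** Sweep currents follow a Boltzmann-gated ohmic
  model `I(V) = g_max (V - V_rev) / (1 + exp(-(V - V_half)/k))` plus an
  ohmic leak reversing at 0 mV and Gaussian noise; membrane voltage is the
  command voltage minus the liquid junction potential. p/10 leak sweeps
  are scaled replicas passing only leak current.

What passing tests on these data do **not** show: robustness to real
backgrounds (autofluorescence, out-of-focus haze), to the manual curation
steps an interactive surface editor allows, or to non-Gaussian camera
artefacts. The generator is a sufficiency check for the algorithms, not a
substitute for real-data validation.

## Spot segmentation and morphometry

`detect_spots()` replaces an interactive surface-detection stage with a
deterministic pipeline: per-plane rolling-ball background subtraction
(grayscale opening with a disc of the stated physical diameter) → Gaussian
smoothing at the "surface detail" scale (0.16 µm by default, interpreted
as the smoothing sigma) → thresholding → 26-connected 3D component
labelling → removal of components under 10 voxels → morphometry. Since the
original workflow thresholded manually per image, the default here is Otsu's
method on the smoothed channel, with an absolute override; this is a known
fidelity limit, and no equivalence with the proprietary algorithm is
claimed. Note that an opening-based rolling ball removes structures *larger*
than the ball: the per-channel ball diameters used for real stainings are
only meaningful when puncta are smaller than the ball, and background
subtraction is off by default for clean synthetic stacks.

Morphometry per component:

* **Volume** is voxel count x voxel volume.
* **Surface area** comes from a marching-tetrahedra isosurface (Kuhn
  triangulation of each grid cell) of the binary mask at level 0.5, after
  smoothing the indicator with an isotropic-physical-scale Gaussian of
  0.8 x the smallest voxel edge. The mild smoothing suppresses the
  staircase overestimate of digitized surfaces (a raw binary mesh
  overestimates a sphere's area by ~28%) while keeping flat faces in
  place; with it, a digitized 1 µm-diameter ball at 20 nm voxels yields
  Wadell sphericity 0.99 and a 2 µm cube 0.82 against the closed form
  0.806. Voxel-face counting is kept in the test suite as a brute-force
  oracle only — it biases sphericity low by construction.
* **Wadell sphericity** is `pi^(1/3) (6V)^(2/3) / A`; 1 for a ball,
  lower for plates — the statistic used to contrast compact RIBEYE puncta
  with plate-like Bassoon structures.
* The **boundary** of each spot is stored as the isosurface triangle
  vertices: sub-voxel surface samples. Surface-to-surface distances are
  minima over these point sets, which is what makes the 0.045/0.06 µm
  proximity classes resolvable at all — distances between boundary *voxel
  centres* are quantized to the voxel pitch (80/200 nm), coarser than the
  classes themselves. Whether the original distances were
  boundary-to-boundary or centre-based is not documented; we use
  boundary-to-boundary.

Filters are inclusive at both volume bounds (0.02 and 2 µm³), ties in
proximity pairing break toward the smaller reference id, and
classification at most one partner per query spot. These conventions are
deliberate choices where the source workflow is silent.

## Pixel colocalization

`pearson_pixel()`, `manders()` and `costes_test()` work on the 1 µm
peripheral ring defined by `build_cell_geometry()` (an inward band of the
stated physical thickness, from a per-plane Euclidean distance transform
of the filled membrane outline; per-cell values average at least three
central planes, excluding the basal and top plane). Manders coefficients
are the *thresholded* variant with Costes auto-thresholds by default
(largest thresholds for which the sub-threshold Pearson correlation is
non-positive, searched down the regression line of B on A); fixed
thresholds are available since the original report does not state which
variant was used. The Costes significance test scrambles square blocks of
channel B within the analysis region and reports the one-sided p-value
`P(r_scramble >= r_observed)` over 100 repetitions; the block side
defaults to 4 px (~3 x the lateral PSF sigma at 80 nm pixels), another
undocumented parameter made explicit here. Under block-independent nulls
the test is calibrated (≥ 90% of null cells give p ≥ 0.05 in the
acceptance suite); for truly colocalized channels the observed r exceeds
all 100 scrambles and p = 0.

## Stimulus-locked ΔF/F

The calcium module mirrors the stimulus-locked workflow exactly:
background subtraction (mean of a designated cell-free region per frame,
or a per-frame rolling ball); ΔF images as the mean of the first three
stimulated frames minus the mean of the five preceding baseline frames,
with a 3 x 3 unweighted smooth *for display only*; circular 2 µm ROIs
whose F0 is the mean of the five pre-stimulus frames; and
`ΔF_max/F0` as the mean of ΔF/F0 over the three frames starting at the
within-window peak. "First three frames of peak signal at stimulation
onset" is ambiguous when the peak falls in the last two window frames; we
shift the 3-frame average back so it stays inside the window, and record
the frames used. ROI classes (with/without a synthetic ribbon) are
assigned from the structural channel alone — the API never sees the
indicator channel during assignment, enforcing the blinding of the
original protocol. Group comparison is per-cell means followed by a paired
two-sided t-test and the mean percent difference.

The paired-design power check simulates 24 cells at a true response ratio
of 1.26 with log-normal site-to-site variability (sigma_log = 0.25) and
per-frame trace noise of 1 a.u. at F0 = 100 — chosen once as a realistic
dispersion for this assay (a paired design at this n and effect detects
the difference in >80% of replicates, consistent with the borderline
p-values such experiments produce).

## IV relations and quality control

Voltages are corrected offline for the liquid junction potential (21.2 or
18 mV depending on the internal solution); the default protocol spans
-86.2 to +58.8 mV in 5 mV steps after correction. Leak subtraction uses
baseline-referenced p/10 sweeps (test minus 10 x the averaged scaled leak
response), which nulls a purely ohmic cell identically. The IV value per
sweep is the mean current 5-10 ms after step onset; densities divide by
Cm. QC discards recordings with |leak| > 50 pA, Rs > 15 MOhm, offset
drift > 5 mV, peak inward current below 49 pA, or peak inward density
above 60 pA/pF — the last two printed with ambiguous signs in the source
protocol and implemented here as magnitude readings ("too small a
current" and "too large a density"), with configurable thresholds. All
rules compare strictly ("exceeded"), so Rs = 15 MOhm passes. The
activation fit uses the same Boltzmann-ohmic form as the generator via
Levenberg-Marquardt least squares; the functional form is a standard
choice for CaV IV relations, not one stated by the source. A recording
with no voltage-dependent current is flagged as non-converged rather than
fitted.

## The statistical decision tree

`compare_two_groups()` runs Jarque-Bera and Kolmogorov-Smirnov normality
tests on each group and an F-test for variance equality, then selects a
two-tailed Student's t-test (paired or unpaired) when **both** groups pass
**both** normality tests at alpha = 0.05 and variances are equal, else
Mann-Whitney-Wilcoxon. The conjunction rule and the alpha are our
explicit choices; the source names the tests but not the gate.
`compare_multi_groups()` generalizes to one-way ANOVA + Tukey HSD versus
Kruskal-Wallis + Dunn; Dunn's z statistics are tie-corrected and
Bonferroni-adjusted over all pairs (the correction family was unnamed in
the source). Descriptives report mean, sample SD, CV = SD/mean (only for
positive means), median and the 10/25/75/90 percentiles that the box-plot
convention draws (boxes 75/25, whiskers 90/10, mean cross, median band,
points overlaid — `plot_box_summary()`). The Jarque-Bera statistic is
implemented directly (`n/6 (S^2 + K^2/4)` against chi-squared with 2 df)
and validated against an independent reference implementation; no
installed R package provides it.

## Numerical choices and degenerate inputs

* Gaussian smoothing uses truncated, edge-renormalized kernels, so
  constant images stay constant up to machine precision.
* Otsu thresholds use a 256-bin histogram between the channel extremes.
* Component labelling offers 6/18/26-connectivity (26 by default).
* Zero-variance traces, all-zero channels, empty spot lists, interior
  means of zero, constant line profiles and identical paired samples all
  return explicit degenerate results (empty tibbles, `NA` with a warning,
  or p = 1) instead of erroring mid-pipeline; genuinely unusable inputs
  (open membrane contours, ROIs off the frame, missing leak sweeps) error
  with a named reason.
* Problem sizes in the test and acceptance suites — 100 digitized
  spheres, a 2 µm cube at 20 nm voxels, 100 simulated cells x 100 Costes
  repetitions, 200 power replicates, 1000 null replicates per statistical
  route, a 5 x 5 activation-parameter grid — were chosen to give stable
  Monte-Carlo estimates at interactive runtimes.

## Known limitations

* The segmentation stage is deterministic; it does not reproduce manual
  curation (adding missed surfaces, splitting merged ones), and Otsu can
  differ substantially from a human-chosen threshold on dim stainings.
* Sphericity at the acquisition voxel size (200 nm z) is biased for
  puncta only a few z-planes thick; closed-form accuracy is reached at
  fine isotropic grids, and comparisons between channels at a fixed grid
  remain meaningful.
* The PSF inflates apparent volumes (a 0.18 µm³ punctum measures
  ~0.5 µm³ under the default blur); the package measures what the image
  shows and performs no deconvolution.
* Costes block scrambling assumes stationarity within the analysis ring;
  strong intensity gradients along the membrane inflate false positives.
* The IV module extracts window means only; inactivation kinetics are out
  of scope.
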