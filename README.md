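# ribbonquant

Quantification toolkit for **synthetic ribbon-type active zones** —
membrane-attached RIBEYE/Bassoon assemblies reconstituted in HEK293 cells
that recruit CaV1.3 Ca²⁺ channels. The package turns the imaging and
electrophysiology readouts of such experiments into reproducible numbers:

* **3D puncta segmentation & morphometry** — rolling-ball background
  subtraction, smoothing, thresholding, 26-connected labelling; per spot:
  volume, isosurface area, Wadell sphericity
  `Ψ = π^(1/3)(6V)^(2/3)/A`, centroid, sub-voxel boundary.
* **Distance-based colocalization** — surface-to-surface distances and
  proximity classes (pairing at ≤ 0.06 µm, ribbon-positive channel
  clusters at ≤ 0.045 µm), paired-volume correlation.
* **Pixel colocalization** — Pearson, thresholded Manders with Costes
  auto-thresholds, Costes block-scramble significance test (100
  repetitions), 1 µm peripheral-ring geometry, peripherality ratio,
  tangential line-profile correlation.
* **Stimulus-locked ΔF/F** — background subtraction, ΔF images
  (3 stimulated minus 5 baseline frames), 2 µm ROI traces,
  `ΔF_max/F₀` (3-frame average at the in-window peak), blinded ROI
  classing, paired per-cell comparison.
* **IV analysis** — liquid-junction-potential correction, p/10 leak
  subtraction, 5–10 ms window extraction, QC exclusion rules, Boltzmann
  activation fits `I(V) = g_max(V−V_rev)/(1+exp(−(V−V_half)/k))` with
  `tidy()`/`glance()` methods.
* **Statistics** — the normality-gated decision tree (Jarque–Bera +
  Kolmogorov–Smirnov + F-test → t-test / Mann–Whitney; ANOVA + Tukey /
  Kruskal–Wallis + Dunn), descriptives with CV and 10/25/75/90
  percentiles, publication-style box plots.
* **Synthetic-data generator** — seeded, ground-truth-annotated image
  stacks (ellipsoidal cell, membrane shell, membrane-anchored punctum
  pairs, Gaussian PSF, Poisson + Gaussian noise), Ca²⁺ time series and
  voltage-clamp recordings, so the whole pipeline is testable end to end.

See `vignettes/ribbon-quantification.Rmd` for the models, parameter
choices and limitations.

## Worked example

```r
library(ribbonquant)

cfg   <- sim_config(seed = 42)                      # 80/80/200 nm voxels
pairs <- membrane_spot_pairs(cfg, n = 10, seed = 42)
sim   <- generate_cell_stack(cfg, pairs)
sim$stack
#> <image_stack> 96 x 96 x 24 voxels, 3 channel(s): membrane, bassoon, ribeye
#>   voxel size (um): x=0.08 y=0.08 z=0.2

rib <- filter_spots(detect_spots(sim$stack, "ribeye"))$kept
bas <- filter_spots(detect_spots(sim$stack, "bassoon"))$kept
describe_values(rib$volume)
#> # A tibble: 1 x 9
#>       n  mean     sd     cv median   p10   p25   p75   p90
#>   <int> <dbl>  <dbl>  <dbl>  <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1    10 0.490 0.0100 0.0204  0.490 0.481 0.487 0.495 0.503

paired <- classify_by_proximity(rib, bas, threshold = 0.06)
sum(paired$colocalized)
#> [1] 10
```

All ten RIBEYE-like puncta pair with their Bassoon-like partners at the
0.06 µm class. The measured volumes (~0.49 µm³ for a 0.18 µm³ punctum)
show the PSF inflation discussed in the vignette; sphericity is ~0.97 for
these spherical ground-truth shapes.

```r
rec <- generate_iv_recording(vhalf = -15, slope_k = 8, seed = 42)
iv  <- extract_iv(correct_ljp(leak_correct_p10(rec)))   # 5-10 ms window
fit_activation(iv)
#> <activation_fit> V_half=-14.67 mV, k=8.29 mV, g_max=1.985 nS, V_rev=60.5 mV
qc_filter(rec, iv)$pass
#> [1] TRUE

compare_two_groups(rib$volume, bas$volume)
#> <group_test> unpaired t-test (route: parametric)
#>   statistic = 21.98, p = 1.872e-14 ****
```

The activation fit recovers the generator's half-activation voltage
(−15 mV) and slope (8 mV) to within the noise, the recording passes every
QC rule, and the decision tree routes the (normal, equal-variance) volume
comparison to an unpaired t-test — here RIBEYE- and Bassoon-like puncta
were rendered at different sizes, hence the significant difference.

An end-to-end demonstration (simulate → segment → classify → colocalize →
calcium → ephys → stats, with CSV outputs and a manifest) runs via

```r
run_pipeline(run_config(list(seed = 1, out_dir = "demo_run")))
```

or from the shell with `Rscript inst/cli/ribbonquant.R run --seed 1 --out demo_run`.

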