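---
title: "Quantifying 3D myelin wrapping on artificial-axon arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D myelin wrapping on artificial-axon arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assay and its readout

Artificial axons (AAs) are vertical hydrogel micropillars — roughly 8 µm in
diameter, ~20 µm tall, printed on a square grid at 20 µm centre-to-centre
spacing — that mimic the geometry and stiffness of biological axons.
Oligodendrocytes seeded on such an array wrap MBP-positive membrane around
the pillars, and the extent of that wrapping, imaged as multi-channel
confocal z-stacks (10 slices at a 2 µm step), is the phenotypic readout of a
pro-myelination screen.

`axonwrap` implements the analysis from binary masks to compound ranking:

1. **Segmentation.** Each channel (axon, myelin, nuclei) is thresholded per
   z-slice (Otsu by default, with a fixed-value override). In-plane
   connected components use 8-connectivity. Pillar components are linked
   across z by XY centroid proximity — the pillars are vertical, so no
   general 3D tracking is needed. Components touching the image border are
   flagged and excluded: their circumference is not fully observable, which
   would bias wrap fractions downward.
2. **Wrap fraction.** For each axon and slice, a 1-px inner outline is
   traced (the region minus its erosion by a 3×3 box; pixels outside the
   image count as background). The *overlap mask* assigns 255 to outline
   pixels that are myelin-positive and 0 to outline pixels without myelin;
   the wrap fraction is the 255-share of the outline — the fraction of the
   circumference covered by myelin in that slice.
3. **z-aggregation.** Maximal runs of consecutive slices with wrap fraction
   strictly above 0.8 become *myelin segments* of length
   `n_slices × z_step` µm. An axon is *fully wrapped* when some segment
   reaches 6 µm — exactly three consecutive >80% slices at the 2 µm step.
   Slices where the pillar region is undetected break contiguity: absence
   of the mask means the circumference is unmeasurable there, so we take
   the conservative reading.
4. **Wrapping index.** Per field of view: fully wrapped axons divided by
   the nuclei count (counted as 8-connected components on the
   maximum-intensity projection of the nuclei masks). Normalizing by cell
   number absorbs local density variation between well regions.
5. **Dose–response.** Condition means (± SEM) over all fields of all
   replicate wells are fitted with a four-parameter logistic
   `R(c) = bottom + (top − bottom)/(1 + (EC50/c)^hill)`. Efficacy is the
   maximum *observed* condition mean — deliberately read from the data
   points, never from the fitted top. Relative efficacy divides by the
   reference compound (thyroid hormone T3), which is pinned at exactly 1.
   Compounds are ranked by efficacy, with adjacent compounds tied when a
   two-group one-way ANOVA on field-level responses at their peak doses
   cannot separate them (p ≥ 0.05, unadjusted by default).
6. **Sheath lengths.** All >80% segments at a condition are pooled (one
   entry per segment, not per axon) and summarized as boxplot statistics
   (quantiles by linear interpolation; whiskers at Q1 − 1.5 IQR and
   Q3 + 1.5 IQR) and as histograms of lengths ≥ 6 µm with 2 µm bins — one
   z-step, since lengths are quantized at z-step resolution. The wrapping
   index can be recomputed under a stricter length threshold (e.g. 10 µm),
   which separates compounds that induce many short sheaths from those
   inducing fewer, longer ones.

## Interpretive choices

Some aspects of the quantification admit more than one reading; the package
fixes them as follows.

* **Category binning.** Axons are binned by their *maximum* per-slice wrap
  fraction into 0–20 / 20–50 / 50–80 / 80–100% (edges
  `[0, 0.2], (0.2, 0.5], (0.5, 0.8], (0.8, 1]`), making the four categories
  mutually exclusive so that per-condition percentages sum to 100%. The
  alternative — counting an axon in every category it touches in some slice
  — is implementable from the per-slice fractions but is not the default.
  Category tallies run over *myelin-engaged* axons (maximum fraction > 0).
* **Strict vs inclusive thresholds.** The per-slice coverage threshold is
  strict (> 0.8): a slice at exactly 80% does not open a segment. The
  length threshold is inclusive (≥ 6 µm), the only reading consistent with
  "three z-slices" at a 2 µm step. Segment length is
  `slice-count × z_step`, not `(count − 1) × z_step`.
* **Cytotoxicity exclusion.** High doses can kill cells; the fit must not
  treat the resulting response collapse as pharmacology. A concentration is
  excluded when its mean nuclei count drops below 50% of the vehicle's, and
  every higher concentration is excluded with it. The 50% cutoff is this
  package's default — the assay literature reports that exclusions happen
  but not a rule.
* **EC50 plateau check.** An EC50 is only meaningful when the response
  levels off within the tested range. The fitted EC50 is withheld when the
  fit fails, when the observed maximum sits at the highest tested dose
  while the fitted top exceeds it by more than 20% (a still-rising series),
  or when the fitted EC50 is at or beyond the highest included dose.
* **Relative-efficacy SEM** uses first-order ratio propagation,
  `rel × sqrt(cv_compound² + cv_reference²)`, applied uniformly — including
  to the reference against itself, whose value is exactly 1 but whose
  uncertainty is still reported.

## Numerical choices

* **4PL fitting** is Levenberg–Marquardt least squares in log-EC50 space,
  initialized at bottom = min mean, top = max mean, EC50 = geometric mean of
  the tested concentrations, hill = 1. EC50 is constrained to
  `[c_min/100, c_max×100]`; the Hill slope to `[0.1, 10]`, which prevents
  bottom/top label switching on noisy series. The vehicle (concentration 0)
  row is carried as a baseline but not fitted; no baseline subtraction is
  applied, because the wrapping index is reported directly. Unweighted
  least squares on condition means is appropriate because field counts are
  balanced by design. A flat series (top = bottom) is reported as a
  non-converged fit with undetermined EC50.
* **Thresholding guard.** Per-slice Otsu misbehaves on slices that contain
  no structures at all: it will happily split pure noise and flood the
  mask. A slice whose foreground/background mean separation falls below
  `threshold_min_contrast` (default 0.1 on the [0, 1] intensity scale) is
  declared all-background with a warning, as is a constant-intensity slice.
* **Ties and degenerate inputs.** Pairwise ANOVA with fewer than three
  observations has no residual degrees of freedom; such pairs are treated
  as indistinguishable (tied). A field with zero nuclei has an undefined
  wrapping index and is flagged invalid and dropped from aggregation, with
  a warning. An empty sheath-length set is an error rather than a silent
  zero.

## What the synthetic generator emulates — and what it does not

No raw microscopy from the original screen is redistributable, so
`generate_field()` renders fields with exact ground truth: filled pillar
discs on the square grid in every slice the pillar spans; myelin as annular
arcs concentric with each pillar, whose angular extent equals the requested
per-slice coverage (start angle random per axon and slice, since results
must not depend on azimuth); nuclei as non-overlapping blobs in the middle
slice; a constant background plus additive Gaussian noise, clipped to
[0, 1]. `generate_plate()` assigns per-axon coverage profiles so that the
expected wrapping index of each condition equals a 4PL in concentration,
yielding a full screen with known EC50s, efficacies, and (optionally)
dose-dependent nuclei loss for the cytotoxicity path.

Simulation defaults mirror the assay design: 0.65 µm/px (a 20× air
objective; the true sampling is not published, so this is configurable),
512×512 fields, 10 slices at 2 µm, 8 µm pillars at 20 µm spacing, 40 nuclei
per field, 9-point 3× dilution series from 10 µM, triplicate wells, vehicle
= solvent-only baseline. The pillar grid is centred with a margin so
rendered pillars never touch the border; border handling is exercised with
hand-built masks instead.

Two deliberate simplifications matter for interpreting green tests:

* **No optics.** There is no PSF, no photobleaching, no axial blur, no
  cell-body morphology; noise is additive Gaussian on a constant
  background, not Poisson. Tests passing on these images show the
  *quantification logic* is correct, not that segmentation is robust to
  real confocal artifacts.
* **Crisp coverage values.** A rasterized arc on a finite outline
  reproduces the requested angular coverage only to ~1–2 outline pixels
  (≈ 0.03–0.08 depending on sampling). The coverage sampler therefore
  draws values keeping a margin around the 0.8 decision boundary (≤ 0.72
  or ≥ 0.87), so ground-truth full-wrap labels remain well defined under
  rasterization. Recovery tests at the strict 0.05 accuracy level use
  0.325 µm/px (Nyquist-type confocal sampling), where the discretization
  term is negligible; at 0.65 µm/px the appropriate tolerance is
  `2/outline-pixels + 0.05`.

## Problem sizes used in the checks

Deterministic definitional checks run on toy masks (21–31 px discs and
squares). Recovery checks use single 256–512 px fields with 64 pillars.
The end-to-end screen check simulates 2 compounds (EC50 50 vs 500 nM, equal
tops) × 9 concentrations × 3 wells × 3 fields at 256×256 px — a deliberate
scale-down of the real 60-well, 9-field screen that keeps every structural
element (vehicle, reference, replication, z-geometry) intact. Monte-Carlo
fit validation uses 200 seeded repeats with field-level noise at 10% of the
top response averaged over 27 fields per condition, the assay's stated
replication (3 wells × 9 fields).

## Known limitations

* Wrapping turn count and compact-myelin ultrastructure are not measured —
  the assay observes an MBP-positive membrane ring, not its lamellar
  structure.
* Nuclei viability is not assessed; all DAPI-positive nuclei count toward
  the denominator.
* The 2D differentiation readout reports total MBP-positive area per field
  of view, unnormalized (a per-nuclei switch exists but is off by default,
  as no normalization is described for the original 2D assay).
* Sheath pooling takes every segment of every axon; pooling one segment
  (e.g. the longest) per axon is a plausible alternative the package does
  not default to.
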